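#' Minimum (histogram-valley) threshold for a bimodal grayscale histogram
#'
#' Iteratively smooths a 256-bin intensity histogram with a 3-bin mean filter
#' until exactly two local maxima remain, then returns the intensity of the
#' minimum-count bin strictly between the two modes. This is the classic
#' minimum-thresholding scheme for separating bone from background in
#' bimodal CT histograms. Ties in the valley are broken toward the lower
#' intensity; plateaus count as a single mode.
#'
#' @param counts numeric vector of 256 bin counts for intensities 0..255.
#' @param maxIter smoothing iteration cap (default 10000); if the histogram
#'   is still not bimodal at the cap an error is raised.
#' @return the threshold intensity (a value in 0..255). Pixels strictly above
#'   the threshold are classified as bone by [binarizeVolume()] and
#'   [sectionGeometry()].
#' @examples
#' h <- numeric(256); h[31] <- 1000; h[201] <- 800  # spikes at 30 and 200
#' minimumThreshold(h)
#' @export
minimumThreshold <- function(counts, maxIter = 10000L) {
  if (length(counts) != 256L) stop("expected a 256-bin histogram")
  if (any(counts < 0) || sum(counts) == 0) stop("histogram is empty")
  h <- as.numeric(counts)
  for (iter in 0:maxIter) {
    modes <- histModes(h)
    if (length(modes$peakRuns) == 2L) {
      lo <- modes$runEnd[modes$peakRuns[1]]   # last bin of the first mode
      hi <- modes$runStart[modes$peakRuns[2]] # first bin of the second mode
      if (hi - lo < 2L) stop("no valley between the two modes")
      interior <- (lo + 1L):(hi - 1L)
      valley <- interior[which.min(h[interior])]  # ties -> lowest intensity
      return(valley - 1L)  # bin i holds intensity i-1
    }
    if (iter == maxIter) break
    h <- smooth3(h)
  }
  stop("no bimodal structure: histogram never reached two modes")
}

## 3-bin mean filter with edge replication
smooth3 <- function(h) {
  n <- length(h)
  (c(h[1], h[-n]) + h + c(h[-1], h[n])) / 3
}

## Run-compressed local maxima: a run of equal values is a peak if it is
## higher than both neighbouring runs (or at the edge, higher than its one
## neighbour).
histModes <- function(h) {
  r <- rle(h)
  v <- r$values
  k <- length(v)
  runEnd <- cumsum(r$lengths)
  runStart <- runEnd - r$lengths + 1L
  if (k == 1L) return(list(peakRuns = integer(0), runStart = runStart,
                           runEnd = runEnd))
  prev <- c(-Inf, v[-k])
  nxt <- c(v[-1], -Inf)
  peaks <- which(v > prev & v > nxt & v > 0)
  list(peakRuns = peaks, runStart = runStart, runEnd = runEnd)
}

## 256-bin histogram of 8-bit-scale intensities (values clamped to [0,255])
intensityHistogram <- function(x) {
  v <- pmin(pmax(floor(as.numeric(x)), 0), 255)
  tabulate(v + 1L, 256L)
}
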