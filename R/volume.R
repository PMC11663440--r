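#' Binarize a voxel volume and keep the largest bone component
#'
#' Applies the minimum (histogram-valley) threshold to the volume's global
#' 256-bin histogram (or an explicit threshold) and retains only the largest
#' 26-connected foreground component, discarding disconnected debris.
#'
#' @param volume a [VoxelVolume-class].
#' @param threshold \code{"auto"} (default) or an explicit intensity; voxels
#'   strictly above the threshold are foreground.
#' @return logical 3D array of bone voxels.
#' @export
binarizeVolume <- function(volume, threshold = "auto") {
  stopifnot(is(volume, "VoxelVolume"))
  thr <- if (identical(threshold, "auto"))
    minimumThreshold(intensityHistogram(volume@intensities))
  else threshold
  mask <- volume@intensities > thr
  if (!any(mask)) stop("empty foreground after thresholding")
  largestComponent(mask, 26L)
}

#' Align a bone volume to its principal axes
#'
#' Rotates the binary volume so the smallest-inertia (longest geometric)
#' axis maps to z, resampling by nearest neighbour, and flips z if needed so
#' the distal end sits at low z. The grayscale volume is carried through the
#' same transform. Rotation about the long axis remains unresolved until
#' [orientAboutLongAxis()].
#'
#' @param binary logical 3D array from [binarizeVolume()].
#' @param gray the matching grayscale array (defaults to the binary mask
#'   scaled to 0/255 if not supplied).
#' @param voxelSize isotropic voxel size in mm.
#' @param distal \code{"auto"} (wider metaphyseal end, judged from the mean
#'   foreground cross-section area of the two end slabs), \code{"low"} or
#'   \code{"high"} flagging where the distal end currently lies on the
#'   aligned z axis.
#' @param provenance id string carried through.
#' @return an [AlignedBone-class].
#' @export
alignPrincipalAxes <- function(binary, gray = NULL, voxelSize,
                               distal = "auto", provenance = NA_character_) {
  d <- dim(binary)
  idx <- which(binary, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty foreground")
  if (any(apply(idx, 2, function(v) diff(range(v))) < 2))
    stop("foreground must span at least 3 voxels in each dimension")
  cv <- stats::cov(idx)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[1] < 1.05 * ev$values[2])
    stop("degenerate inertia tensor: no unambiguous long axis ",
         "(principal variances nearly equal)")
  vz <- ev$vectors[, 1]            # long axis -> z
  if (vz[3] < 0) vz <- -vz         # keep a stable sign convention
  ## remaining axes: pick the one closest to x for x
  v2 <- ev$vectors[, 2]; v3 <- ev$vectors[, 3]
  if (abs(v3[1]) > abs(v2[1])) { tmp <- v2; v2 <- v3; v3 <- tmp }
  if (v2[1] < 0) v2 <- -v2
  vy <- pracmaCross(vz, v2)        # right-handed frame
  Q <- cbind(v2, vy, vz)           # columns: aligned-frame axes in input coords
  if (det(Q) < 0) Q[, 2] <- -Q[, 2]
  if (is.null(gray)) gray <- array(ifelse(binary, 200, 0), d)
  ## out = t(Q) %*% in ; rotateVolumeNN expects R with out = R %*% in
  R <- t(Q)
  bin2 <- rotateVolumeNN(array(as.numeric(binary), d), R, 0) > 0.5
  gray2 <- rotateVolumeNN(gray, R, min(gray))
  ## decide distal end
  flip <- FALSE
  zprof <- apply(bin2, 3, sum)
  fg <- which(zprof > 0)
  if (!length(fg)) stop("alignment produced empty volume")
  slab <- max(3L, ceiling(0.1 * length(fg)))
  lowArea <- mean(zprof[fg[seq_len(slab)]])
  highArea <- mean(zprof[fg[seq(length(fg) - slab + 1L, length(fg))]])
  if (identical(distal, "auto")) flip <- highArea > lowArea
  else if (identical(distal, "high")) flip <- TRUE
  else if (!identical(distal, "low")) stop("distal must be auto/low/high")
  if (flip) {
    bin2 <- bin2[, rev(seq_len(dim(bin2)[2])), rev(seq_len(dim(bin2)[3]))]
    gray2 <- gray2[, rev(seq_len(dim(gray2)[2])), rev(seq_len(dim(gray2)[3]))]
    zprof <- rev(zprof)
    fg <- which(zprof > 0)
  }
  len <- (max(fg) - min(fg) + 1L) * voxelSize
  new("AlignedBone", binaryVolume = bin2, grayVolume = gray2,
      voxelSize = voxelSize, rotationApplied = Q, lengthMm = len,
      provenance = provenance)
}

pracmaCross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

## angle (deg) between the foreground principal axis and z
longAxisDeviation <- function(binary) {
  idx <- which(binary, arr.ind = TRUE)
  ev <- eigen(stats::cov(idx), symmetric = TRUE)
  v <- ev$vectors[, 1]
  acos(min(abs(v[3]) / sqrt(sum(v^2)), 1)) * 180 / pi
}

#' Orient an aligned bone about its long axis
#'
#' Deterministic surrogate for manual landmark rotation: rotates about z so
#' that the major principal axis of the distal-most 5 percent-of-length
#' slab's summed cross-section lies along x (mediolateral). An explicit
#' angle (degrees) overrides the rule. Left-side bones are mirrored across x
#' first so all specimens share one handedness.
#'
#' @param aligned an [AlignedBone-class].
#' @param mode \code{"distal-section-axis"} (default) or a numeric angle in
#'   degrees (rotation about z).
#' @param side \code{"right"} (default) or \code{"left"}; left-side volumes
#'   are mirrored across the x axis.
#' @return the re-oriented [AlignedBone-class].
#' @export
orientAboutLongAxis <- function(aligned, mode = "distal-section-axis",
                                side = "right") {
  stopifnot(is(aligned, "AlignedBone"))
  bin <- aligned@binaryVolume
  gray <- aligned@grayVolume
  if (identical(side, "left")) {
    bin <- bin[rev(seq_len(dim(bin)[1])), , ]
    gray <- gray[rev(seq_len(dim(gray)[1])), , ]
  } else if (!identical(side, "right")) stop("side must be right or left")
  if (is.numeric(mode)) {
    ang <- mode
  } else if (identical(mode, "distal-section-axis")) {
    zprof <- apply(bin, 3, sum)
    fg <- which(zprof > 0)
    slab <- fg[seq_len(max(1L, ceiling(0.05 * length(fg))))]
    w <- apply(bin[, , slab, drop = FALSE], c(1, 2), sum)
    tot <- sum(w)
    xs <- seq_len(nrow(w)); ys <- seq_len(ncol(w))
    xb <- sum(rowSums(w) * xs) / tot
    yb <- sum(colSums(w) * ys) / tot
    mu20 <- sum(w * outer((xs - xb)^2, rep(1, ncol(w)))) / tot
    mu02 <- sum(w * outer(rep(1, nrow(w)), (ys - yb)^2)) / tot
    mu11 <- sum(w * outer(xs - xb, ys - yb)) / tot
    if (sqrt((mu20 - mu02)^2 + 4 * mu11^2) < 1e-3 * (mu20 + mu02)) {
      warning("distal section is circular: axis undefined, no rotation applied")
      ang <- 0
    } else {
      ang <- -0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
    }
  } else stop("mode must be 'distal-section-axis' or a numeric angle")
  if (abs(ang) > 1e-9) {
    bin <- rotateVolumeAboutZ(array(as.numeric(bin), dim(bin)), ang, 0) > 0.5
    gray <- rotateVolumeAboutZ(gray, ang, min(gray))
  }
  zprof <- apply(bin, 3, sum)
  fg <- which(zprof > 0)
  len <- (max(fg) - min(fg) + 1L) * aligned@voxelSize
  new("AlignedBone", binaryVolume = bin, grayVolume = gray,
      voxelSize = aligned@voxelSize,
      rotationApplied = aligned@rotationApplied %*% t(rotZ(ang)),
      lengthMm = len, provenance = aligned@provenance)
}

#' Intermetaphyseal length of an aligned bone
#'
#' The foreground z-extent: (max z index - min z index + 1) x voxel size.
#'
#' @param aligned an [AlignedBone-class].
#' @return length in mm.
#' @export
intermetaphysealLength <- function(aligned) {
  stopifnot(is(aligned, "AlignedBone"))
  zprof <- apply(aligned@binaryVolume, 3, sum)
  fg <- which(zprof > 0)
  (max(fg) - min(fg) + 1L) * aligned@voxelSize
}

#' Extract a cross-section at a length fraction
#'
#' Returns the grayscale slice at foreground z index
#' \code{zmin + round(fraction * (nSlices - 1))} counted from the distal
#' (low z) end, with half-way values rounded away from zero.
#'
#' @param aligned an [AlignedBone-class].
#' @param fraction length fraction strictly inside (0, 1).
#' @return a [CrossSectionImage-class].
#' @export
extractSection <- function(aligned, fraction) {
  stopifnot(is(aligned, "AlignedBone"))
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly inside (0, 1)")
  zprof <- apply(aligned@binaryVolume, 3, sum)
  fg <- which(zprof > 0)
  zmin <- min(fg); n <- max(fg) - zmin + 1L
  k <- zmin + roundHalfUp(fraction * (n - 1L))
  new("CrossSectionImage", intensities = aligned@grayVolume[, , k],
      pixelSize = aligned@voxelSize,
      provenance = sprintf("%s_f%02d", aligned@provenance,
                           round(100 * fraction)))
}
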