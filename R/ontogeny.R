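#' Locomotor stage definitions
#'
#' Five age-defined developmental stages tracking the chimpanzee locomotor
#' transitions from being carried, through arboreal/suspensory locomotion,
#' to predominantly terrestrial quadrupedalism. Boundaries are half-open
#' intervals [low, high) in years so the bins are exhaustive and
#' non-overlapping on [0, 13).
#'
#' @return data frame with stage id, ageLow, ageHigh and a label.
#' @export
locomotorStages <- function() {
  data.frame(
    stage = 1:5,
    ageLow = c(0, 5 / 12, 3, 5, 10),
    ageHigh = c(5 / 12, 3, 5, 10, 13),
    label = c("carried (0-4.9 mo)", "early independent (5 mo-2.9 y)",
              "increasing quadrupedalism (3-4.9 y)",
              "independent juvenile (5-9.9 y)",
              "near-adult locomotion (10-13 y)"),
    stringsAsFactors = FALSE)
}

#' Assign locomotor stage from age
#'
#' @param ageYears numeric vector of ages in years, each within [0, 13).
#' @return integer vector of stage ids (1 to 5).
#' @examples
#' assignStage(c(0.04, 3.76, 12.57))  # 1, 3, 5
#' @export
assignStage <- function(ageYears) {
  if (any(ageYears < 0 | ageYears >= 13))
    stop("age outside [0, 13): no locomotor stage defined")
  st <- locomotorStages()
  findInterval(ageYears, c(st$ageLow, 13), rightmost.closed = FALSE)
}

#' Fit a LOESS ontogenetic trend curve
#'
#' Locally weighted regression (tricube kernel) over the span fraction of
#' nearest neighbours, evaluated on a 100-point grid over the observed age
#' range, with pointwise 95 percent intervals from the local fit's variance
#' estimate. The local polynomial degree defaults to 2 (local quadratic):
#' with span 0.7 over a full ontogenetic age range a local-linear fit cannot
#' represent an interior infancy peak (its one-sided boundary windows pin
#' the fitted maximum to the range edge even for noise-free data), while a
#' local quadratic tracks both the peak and monotone segments.
#'
#' @param ages numeric predictor (years), at least 8 points, not all equal.
#' @param values numeric response.
#' @param span LOESS span (fraction of points in each local window).
#' @param degree local polynomial degree, 1 or 2.
#' @return a [TrendFit-class].
#' @export
loessTrend <- function(ages, values, span = 0.7, degree = 2) {
  if (length(ages) != length(values)) stop("ages and values differ in length")
  if (length(ages) < 8L) stop("need at least 8 points for a trend fit")
  if (diff(range(ages)) == 0) stop("ages must not all be equal")
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  if (floor(span * length(ages)) < degree + 2L)
    stop("span window supports too few points for the local fit")
  df <- data.frame(age = ages, value = values)
  fit <- stats::loess(value ~ age, data = df, span = span, degree = degree,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(ages), max(ages), length.out = 100)
  pr <- stats::predict(fit, newdata = data.frame(age = grid), se = TRUE)
  hw <- stats::qt(0.975, pr$df) * pr$se.fit
  new("TrendFit", grid = grid, fitted = as.numeric(pr$fit),
      halfWidth = as.numeric(hw), span = span, degree = degree,
      n = length(ages))
}

#' Age of the fitted trend's maximum
#'
#' Grid argmax of a [TrendFit-class]'s fitted values; used to locate the
#' ontogenetic peak of rise-then-fall parameters such as the medullary
#' index.
#'
#' @param trend a [TrendFit-class].
#' @return age (years) of the fitted maximum.
#' @export
trendPeakAge <- function(trend) {
  trend@grid[which.max(trend@fitted)]
}

#' Is a fitted trend non-increasing beyond an age, within its uncertainty?
#'
#' Checks that beyond \code{fromAge} the fitted curve never rebounds above
#' its running minimum by more than the pointwise 95 percent half-width:
#' a monotone-decline check tolerant of smoothing wiggles that are within
#' the fit's own uncertainty.
#'
#' @param trend a [TrendFit-class].
#' @param fromAge age (years) after which decline is expected.
#' @return logical.
#' @export
trendNonIncreasingAfter <- function(trend, fromAge) {
  i <- trend@grid >= fromAge
  if (!any(i)) return(TRUE)
  f <- trend@fitted[i]
  all(f - cummin(f) <= trend@halfWidth[i])
}

#' Per-stage Tukey box-plot summaries
#'
#' For each represented locomotor stage: n, mean, median, quartiles (linear
#' interpolation), Tukey whiskers (most extreme values within 1.5 x IQR of
#' the quartiles) and outliers beyond the whiskers.
#'
#' @param ages numeric ages in years.
#' @param values numeric parameter values, same length.
#' @return data frame with one row per represented stage and a list column
#'   \code{outliers}.
#' @export
stageSummaries <- function(ages, values) {
  if (length(ages) != length(values)) stop("ages and values differ in length")
  stage <- assignStage(ages)
  out <- lapply(sort(unique(stage)), function(s) {
    v <- values[stage == s]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    loFence <- q[1] - 1.5 * iqr
    hiFence <- q[3] + 1.5 * iqr
    inFence <- v[v >= loFence & v <= hiFence]
    data.frame(stage = s, n = length(v), mean = mean(v), median = q[2],
               q1 = q[1], q3 = q[3],
               whiskerLow = min(inFence), whiskerHigh = max(inFence),
               outliers = I(list(sort(v[v < loFence | v > hiFence]))))
  })
  do.call(rbind, out)
}

#' Cohort-level ontogenetic analysis
#'
#' Joins specimen metadata with per-section geometry records, assigns
#' locomotor stages, and fits LOESS trends plus stage summaries of the four
#' size-independent parameters (Imax/Imin, Ix/Iy, medullary index, porosity
#' index) per section location. Deterministic and invariant to specimen
#' order.
#'
#' @param metadata data frame with columns \code{id} and \code{age_years}
#'   (other columns are carried through).
#' @param records data frame of section records with columns \code{id},
#'   \code{fraction} and the four index columns named as in
#'   [as.data.frame.SectionGeometry()].
#' @param span LOESS span (default 0.7).
#' @param degree local polynomial degree (default 2, see [loessTrend()]).
#' @return list with \code{results} (tidy per specimen x fraction table,
#'   ordered by id then fraction), \code{trends} (named list of
#'   [TrendFit-class], names \code{<parameter>_f<fraction>}), and
#'   \code{stageSummaries} (long data frame over parameter x fraction).
#' @export
runCohortAnalysis <- function(metadata, records, span = 0.7, degree = 2) {
  needMeta <- c("id", "age_years")
  if (!all(needMeta %in% names(metadata)))
    stop("metadata needs columns: ", paste(needMeta, collapse = ", "))
  params <- c("imax_imin_ratio", "ix_iy_ratio", "medullary_index",
              "porosity_index")
  need <- c("id", "fraction", params)
  if (!all(need %in% names(records)))
    stop("records needs columns: ", paste(need, collapse = ", "))
  fractions <- sort(unique(records$fraction))
  missing <- unlist(lapply(metadata$id, function(i) {
    have <- records$fraction[records$id == i]
    if (!all(fractions %in% have)) i else NULL
  }))
  if (length(missing))
    stop("specimens missing section records: ",
         paste(missing, collapse = ", "))
  res <- merge(metadata, records, by = "id")
  res$stage <- assignStage(res$age_years)
  res <- res[order(res$id, res$fraction), , drop = FALSE]
  rownames(res) <- NULL

  trends <- list()
  summaries <- list()
  for (f in fractions) {
    sub <- res[res$fraction == f, , drop = FALSE]
    for (p in params) {
      key <- sprintf("%s_f%02d", p, round(100 * f))
      trends[[key]] <- loessTrend(sub$age_years, sub[[p]], span = span,
                                  degree = degree)
      ss <- stageSummaries(sub$age_years, sub[[p]])
      ss$parameter <- p
      ss$fraction <- f
      summaries[[key]] <- ss
    }
  }
  list(results = res, trends = trends,
       stageSummaries = do.call(rbind, summaries))
}
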