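#' Fit the cubic femur-length growth curve
#'
#' Ordinary least-squares fit of FL(a) = c0 + c1 a + c2 a^2 + c3 a^3 (femur
#' length in mm on age in years), following the convention of plotting
#' length against age and inverting numerically for age estimation.
#' Monotonicity is checked on a 1000-point grid of the observed age range;
#' a non-monotone fit triggers a warning and is flagged on the returned
#' object.
#'
#' @param pairs data frame with columns \code{age_years} and
#'   \code{femur_length_mm}; at least 4 distinct ages.
#' @return a [GrowthCurve-class].
#' @export
fitGrowthCurve <- function(pairs) {
  need <- c("age_years", "femur_length_mm")
  if (!all(need %in% names(pairs)))
    stop("pairs needs columns: ", paste(need, collapse = ", "))
  age <- pairs$age_years
  fl <- pairs$femur_length_mm
  if (length(unique(age)) < 4L)
    stop("need at least 4 distinct ages to fit a cubic")
  fit <- stats::lm(fl ~ stats::poly(age, 3, raw = TRUE))
  co <- unname(stats::coef(fit))
  if (any(!is.finite(co))) stop("rank-deficient design: cubic not identifiable")
  names(co) <- c("c0", "c1", "c2", "c3")
  ageRange <- range(age)
  grid <- seq(ageRange[1], ageRange[2], length.out = 1000)
  mono <- all(diff(evalGrowthCurve(co, grid)) > 0)
  if (!mono)
    warning("fitted growth curve is not strictly increasing on the ",
            "observed age range; age estimates may be ambiguous")
  new("GrowthCurve", coefficients = co, ageRange = ageRange,
      lengthRange = range(fl), monotone = mono)
}

evalGrowthCurve <- function(co, age) {
  co <- unname(co)
  co[1] + co[2] * age + co[3] * age^2 + co[4] * age^3
}

#' Predict femur length from age
#'
#' @param curve a [GrowthCurve-class].
#' @param ageYears ages in years.
#' @return femur lengths in mm.
#' @export
predictLength <- function(curve, ageYears) {
  stopifnot(is(curve, "GrowthCurve"))
  evalGrowthCurve(curve@coefficients, ageYears)
}

#' Estimate age from femur length
#'
#' Solves FL(a) = femur length by bisection over the curve's valid age
#' range (the root is unique when the curve is monotone). Lengths are
#' accepted within the observed length range extended by 5 percent of its
#' width; anything beyond is refused as extrapolation. The returned age is
#' full precision; round to 2 decimals for reporting.
#'
#' @param curve a [GrowthCurve-class].
#' @param femurLengthMm femur length in mm (scalar or vector).
#' @return estimated ages in years.
#' @export
estimateAge <- function(curve, femurLengthMm) {
  stopifnot(is(curve, "GrowthCurve"))
  vapply(femurLengthMm, function(fl) {
    slack <- 0.05 * diff(curve@lengthRange)
    if (fl < curve@lengthRange[1] - slack || fl > curve@lengthRange[2] + slack)
      stop(sprintf(
        "extrapolation: femur length %.1f mm outside calibrated range [%.1f, %.1f] (+/- 5%% slack)",
        fl, curve@lengthRange[1], curve@lengthRange[2]))
    co <- curve@coefficients
    lo <- curve@ageRange[1] - 0.1 * diff(curve@ageRange)
    hi <- curve@ageRange[2] + 0.1 * diff(curve@ageRange)
    grid <- seq(lo, hi, length.out = 2000)
    fv <- evalGrowthCurve(co, grid) - fl
    sgn <- sign(fv)
    cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    if (length(cross) == 0) {
      hit <- which(fv == 0)
      if (length(hit)) return(grid[hit[1]])
      stop("extrapolation: femur length not attained on the valid age range")
    }
    if (length(cross) > 1 && !curve@monotone) {
      roots <- vapply(cross, function(i)
        stats::uniroot(function(a) evalGrowthCurve(co, a) - fl,
                       c(grid[i], grid[i + 1]), tol = 1e-10)$root, 0)
      stop("non-monotone curve: multiple candidate ages ",
           paste(sprintf("%.2f", roots), collapse = ", "))
    }
    i <- cross[1]
    stats::uniroot(function(a) evalGrowthCurve(co, a) - fl,
                   c(grid[i], grid[i + 1]), tol = 1e-10)$root
  }, numeric(1))
}

#' Simulate (age, femur length) calibration pairs
#'
#' Ages are drawn uniformly over the curve's valid age range and lengths
#' are the curve values plus Gaussian noise; used for growth-model
#' validation and synthetic cohorts.
#'
#' @param curve a [GrowthCurve-class].
#' @param n number of pairs (>= 4 so a cubic refit is identifiable).
#' @param noiseSd Gaussian length noise sd in mm.
#' @param seed RNG seed.
#' @return data frame with \code{age_years} and \code{femur_length_mm}.
#' @export
simulateGrowthPairs <- function(curve, n, noiseSd = 0, seed = 1L) {
  stopifnot(is(curve, "GrowthCurve"))
  if (n < 4L) stop("n must be at least 4 (cubic identifiable)")
  set.seed(seed)
  age <- stats::runif(n, curve@ageRange[1], curve@ageRange[2])
  fl <- predictLength(curve, age) + stats::rnorm(n, 0, noiseSd)
  data.frame(age_years = age, femur_length_mm = fl)
}

#' Reference chimpanzee femur sample metadata
#'
#' The printed ontogenetic sample table bundled with the package: specimen
#' id, sex, age (years), side, femur length (mm), scan resolution (mm),
#' locomotor stage, and the basis of each age (\code{documented} = birth and
#' death dates or dental histology; \code{documented_year} = birth year
#' known to the year only; \code{length_estimated} = age itself estimated
#' from femur length). The \code{length_estimated} rows must be excluded
#' when calibrating a growth curve.
#'
#' @return data frame of the 20-individual sample.
#' @export
chimpFemurSample <- function() {
  path <- system.file("extdata", "chimp_femur_sample.csv",
                      package = "boneCSG", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Default growth-curve calibration pairs from the reference sample
#'
#' Returns the known-age rows (documented plus year-only ages; 16
#' individuals), excluding the rows whose ages were themselves estimated
#' from femoral length.
#'
#' @param includeYearOnly include the five year-only ages (default TRUE).
#' @return data frame with \code{id}, \code{age_years},
#'   \code{femur_length_mm}.
#' @export
growthCalibrationPairs <- function(includeYearOnly = TRUE) {
  s <- chimpFemurSample()
  keep <- s$age_basis == "documented" |
    (includeYearOnly & s$age_basis == "documented_year")
  s[keep, c("id", "age_years", "femur_length_mm")]
}
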