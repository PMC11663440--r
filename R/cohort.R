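#' Ontogenetic trajectory functions
#'
#' Smooth age trajectories of the three size-independent parameters used by
#' the cohort generator. They emulate the qualitative ontogenetic pattern of
#' a growing chimpanzee femur: the medullary index (MA/TA) rises from birth
#' to an infancy/early-juvenile peak and declines toward an adult level with
#' an additional slowly decaying infant excess; the porosity index (CPA/CA)
#' decays exponentially from a high neonatal level to a low plateau; the
#' Ix/Iy ratio declines monotonically from near-circular (1.0) toward a
#' mediolaterally reinforced adult value.
#'
#' Defaults (chosen once as plausible for the modelled system): medullary
#' adult level 0.28, infant excess 0.08 decaying with timescale 4 y, rise
#' amplitude 0.30 peaking at 2.5 y with fall sharpness 3; porosity from 0.25
#' to a 0.02 plateau at rate 0.9/y; Ix/Iy from 1.0 to 0.55 at rate 0.45/y.
#'
#' @param age ages in years.
#' @param pars named parameter vector (see [cohortSpec()] defaults).
#' @return trajectory values at \code{age}.
#' @name trajectories
NULL

#' @rdname trajectories
#' @export
medullaryTrajectory <- function(age,
    pars = c(adultLevel = 0.28, infantExcess = 0.08, excessTau = 4,
             peakAge = 2.5, riseAmplitude = 0.30, fallSharpness = 3)) {
  bump <- ((age / pars[["peakAge"]]) * exp(1 - age / pars[["peakAge"]]))^
    pars[["fallSharpness"]]
  pars[["adultLevel"]] + pars[["infantExcess"]] * exp(-age / pars[["excessTau"]]) +
    pars[["riseAmplitude"]] * bump
}

#' @rdname trajectories
#' @export
porosityTrajectory <- function(age,
    pars = c(initialLevel = 0.25, declineRate = 0.9, plateau = 0.02)) {
  pars[["plateau"]] + (pars[["initialLevel"]] - pars[["plateau"]]) *
    exp(-pars[["declineRate"]] * age)
}

#' @rdname trajectories
#' @export
shapeTrajectory <- function(age,
    pars = c(initialRatio = 1.0, adultRatio = 0.55, declineRate = 0.45)) {
  pars[["adultRatio"]] + (pars[["initialRatio"]] - pars[["adultRatio"]]) *
    exp(-pars[["declineRate"]] * age)
}

#' Age at which the porosity trajectory reaches its plateau
#'
#' Defined as the age where the decaying excess has fallen to 5 percent of
#' its initial amplitude.
#'
#' @param pars porosity trajectory parameters.
#' @return age in years.
#' @export
porosityPlateauOnset <- function(pars = c(initialLevel = 0.25,
                                          declineRate = 0.9, plateau = 0.02)) {
  -log(0.05) / pars[["declineRate"]]
}

#' Default growth curve for synthetic cohorts
#'
#' A monotone cubic with coefficients rounded from a fit to the reference
#' sample (see [growthCalibrationPairs()]): FL(a) = 67.7 + 34.6 a - 3.21 a^2
#' + 0.133 a^3, valid on 0 to 12.6 years.
#'
#' @return a [GrowthCurve-class].
#' @export
defaultGrowthCurve <- function() {
  co <- c(c0 = 67.7, c1 = 34.6, c2 = -3.21, c3 = 0.133)
  grid <- seq(0, 12.6, length.out = 1000)
  new("GrowthCurve", coefficients = co, ageRange = c(0, 12.6),
      lengthRange = range(evalGrowthCurve(co, grid)),
      monotone = all(diff(evalGrowthCurve(co, grid)) > 0))
}

#' Construct a CohortSpec
#'
#' @param nIndividuals cohort size (default 40).
#' @param ageRangeYears uniform age sampling range (default 0.04 to 12.6 y,
#'   the modelled ontogenetic window).
#' @param medullaryTrajectory,porosityTrajectory,shapeTrajectory named
#'   parameter vectors (see [trajectories]).
#' @param growthCurve a [GrowthCurve-class] (default [defaultGrowthCurve()]).
#' @param noiseSds named numeric: \code{medullary} additive sd (default
#'   0.02), \code{porosityCv} lognormal coefficient of variation (default
#'   0.25; porosity scatter in real ontogenetic series is strongly
#'   heteroscedastic, large in infancy and near zero after stabilisation),
#'   \code{shape} additive sd on Ix/Iy (default 0.05), \code{femurLength}
#'   mm sd (default 5).
#' @param seed RNG seed.
#' @return a validated [CohortSpec-class].
#' @export
cohortSpec <- function(nIndividuals = 40,
                       ageRangeYears = c(0.04, 12.6),
                       medullaryTrajectory = c(adultLevel = 0.28,
                                               infantExcess = 0.08,
                                               excessTau = 4, peakAge = 2.5,
                                               riseAmplitude = 0.30,
                                               fallSharpness = 3),
                       porosityTrajectory = c(initialLevel = 0.25,
                                              declineRate = 0.9,
                                              plateau = 0.02),
                       shapeTrajectory = c(initialRatio = 1.0,
                                           adultRatio = 0.55,
                                           declineRate = 0.45),
                       growthCurve = defaultGrowthCurve(),
                       noiseSds = c(medullary = 0.02, porosityCv = 0.25,
                                    shape = 0.05, femurLength = 5),
                       seed = 1L) {
  new("CohortSpec", nIndividuals = nIndividuals,
      ageRangeYears = ageRangeYears,
      medullaryTrajectory = medullaryTrajectory,
      porosityTrajectory = porosityTrajectory,
      shapeTrajectory = shapeTrajectory, growthCurve = growthCurve,
      noiseSds = noiseSds, seed = seed)
}

#' Generate an ontogenetic cohort with exact ground truth
#'
#' Draws ages uniformly over the cohort range, sets femur length from the
#' growth curve plus noise, evaluates the three index trajectories (plus
#' individual scatter) at each age, and derives each individual's phantom
#' geometry from them: with the endocortical ellipse proportional to the
#' periosteal one (scale s), MA/TA = s^2 exactly, and with outer semi-axes
#' (a, b), Ix/Iy = (b/a)^2 exactly, so the planted annuli realise the true
#' index values. Optionally renders the full voxel phantom volume for each
#' individual; cohort-level trend analyses only need the truth records.
#'
#' @param spec a [CohortSpec-class].
#' @param renderVolumes render a [VoxelVolume-class] per individual
#'   (default FALSE; slow for large cohorts).
#' @param voxelSizeMm voxel size for rendered volumes.
#' @return list with \code{metadata} (one row per individual: id, sex, age,
#'   side, femur length, voxel size, stage), \code{truth} (true index values
#'   and geometry per individual), and \code{volumes} (list of
#'   [VoxelVolume-class] or NULL).
#' @export
makeCohort <- function(spec, renderVolumes = FALSE, voxelSizeMm = 0.25) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  set.seed(spec@seed)
  n <- as.integer(spec@nIndividuals)
  age <- stats::runif(n, spec@ageRangeYears[1], spec@ageRangeYears[2])
  fl <- predictLength(spec@growthCurve, age) +
    stats::rnorm(n, 0, spec@noiseSds[["femurLength"]])
  med <- medullaryTrajectory(age, spec@medullaryTrajectory) +
    stats::rnorm(n, 0, spec@noiseSds[["medullary"]])
  med <- pmin(pmax(med, 0.02), 0.9)
  por <- porosityTrajectory(age, spec@porosityTrajectory) *
    exp(stats::rnorm(n, 0, spec@noiseSds[["porosityCv"]]))
  por <- pmin(pmax(por, 0), 0.4)
  shp <- shapeTrajectory(age, spec@shapeTrajectory) +
    stats::rnorm(n, 0, spec@noiseSds[["shape"]])
  shp <- pmin(pmax(shp, 0.2), 1.5)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  side <- sample(c("L", "R"), n, replace = TRUE)
  ## mid-shaft outer ML semi-axis scales with femur length; aspect from the
  ## shape ratio, cavity scale from the medullary index
  aML <- 0.05 * fl
  bAP <- aML * sqrt(shp)
  s <- sqrt(med)
  metadata <- data.frame(
    id = sprintf("SYN_%03d", seq_len(n)), sex = sex, age_years = age,
    side = side, femur_length_mm = fl, voxel_size_mm = voxelSizeMm,
    stage = assignStage(pmin(age, 12.999)))
  truth <- data.frame(
    id = metadata$id, age_years = age, medullary_index = med,
    porosity_index = por, ix_iy_ratio = shp,
    imax_imin_ratio = pmax(shp, 1 / shp),
    outer_a = aML, outer_b = bAP, inner_a = s * aML, inner_b = s * bAP)
  volumes <- NULL
  if (renderVolumes) {
    volumes <- lapply(seq_len(n), function(i) {
      waist <- 0.9
      sp <- phantomSpec(
        lengthMm = 0.6 * fl[i],
        outerProfile = cbind(zFrac = c(0, 0.45, 1),
                             a = aML[i] * c(1.25, waist, 1.1),
                             b = bAP[i] * c(1.25, waist, 1.1)),
        innerProfile = cbind(zFrac = c(0, 0.45, 1),
                             a = s[i] * aML[i] * c(1.25, waist, 1.1),
                             b = s[i] * bAP[i] * c(1.25, waist, 1.1)),
        poreFraction = por[i], voxelSizeMm = voxelSizeMm,
        noiseSd = 5, seed = spec@seed + i)
      makePhantomVolume(sp)$volume
    })
  }
  list(metadata = metadata, truth = truth, volumes = volumes)
}
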