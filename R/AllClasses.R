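#' @import methods
NULL

#' VoxelVolume: a grayscale voxel volume with isotropic spacing
#'
#' Container for a micro-CT style scan surrogate. Intensities are stored as a
#' 3D numeric array indexed \code{[x, y, z]} (x = mediolateral, y =
#' anteroposterior, z = long axis once aligned), with values on an 8-bit
#' grayscale (0--255).
#'
#' @slot intensities 3D numeric array of grayscale values.
#' @slot voxelSize isotropic voxel edge length in mm.
#' @slot provenance specimen id or other origin string.
#' @export
setClass("VoxelVolume",
  representation(intensities = "array", voxelSize = "numeric",
                 provenance = "character"),
  prototype(provenance = NA_character_))

setValidity("VoxelVolume", function(object) {
  msg <- NULL
  if (length(dim(object@intensities)) != 3L)
    msg <- c(msg, "intensities must be a 3D array")
  if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
      object@voxelSize <= 0)
    msg <- c(msg, "voxelSize must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' AlignedBone: a bone volume in the standardized anatomical frame
#'
#' Produced by [alignPrincipalAxes()] (and refined by
#' [orientAboutLongAxis()]). The long axis lies along z with the distal end at
#' low z; x is mediolateral and y anteroposterior after in-plane orientation.
#' Both the binary bone mask and the resampled grayscale volume are carried so
#' that sections can be extracted with full intensity information.
#'
#' @slot binaryVolume logical 3D array, TRUE for bone voxels.
#' @slot grayVolume numeric 3D array, grayscale resampled with the same
#'   transform.
#' @slot voxelSize isotropic voxel edge length in mm.
#' @slot rotationApplied 3x3 rotation matrix mapping aligned-frame
#'   coordinates back into the input frame.
#' @slot lengthMm intermetaphyseal length (foreground z-extent) in mm.
#' @slot provenance specimen id.
#' @export
setClass("AlignedBone",
  representation(binaryVolume = "array", grayVolume = "array",
                 voxelSize = "numeric", rotationApplied = "matrix",
                 lengthMm = "numeric", provenance = "character"),
  prototype(provenance = NA_character_))

setValidity("AlignedBone", function(object) {
  msg <- NULL
  if (!is.logical(object@binaryVolume))
    msg <- c(msg, "binaryVolume must be logical")
  if (!identical(dim(object@binaryVolume), dim(object@grayVolume)))
    msg <- c(msg, "binaryVolume and grayVolume dimensions differ")
  if (object@lengthMm <= 0) msg <- c(msg, "lengthMm must be positive")
  if (is.null(msg)) TRUE else msg
})

#' CrossSectionImage: one 2D diaphyseal cross-section
#'
#' A grayscale slice indexed \code{[x, y]} with x = mediolateral (ML) and y =
#' anteroposterior (AP), pixel-centre coordinates, 0-based physical origin at
#' the image corner.
#'
#' @slot intensities 2D numeric matrix of grayscale values.
#' @slot pixelSize pixel edge length in mm.
#' @slot provenance specimen/section id.
#' @export
setClass("CrossSectionImage",
  representation(intensities = "matrix", pixelSize = "numeric",
                 provenance = "character"),
  prototype(provenance = NA_character_))

setValidity("CrossSectionImage", function(object) {
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    "pixelSize must be a single positive number" else TRUE
})

#' PeriostealContour: the traced subperiosteal outline
#'
#' @slot polygon two-column matrix of closed polygon vertices (mm).
#' @slot enclosedArea area enclosed by the outline in mm^2 (pixel-count
#'   based; the polygon is retained for reporting/plotting).
#' @export
setClass("PeriostealContour",
  representation(polygon = "matrix", enclosedArea = "numeric"))

#' EndocortealEllipse: ellipse approximating the endocortical border
#'
#' A degenerate ellipse (zero semi-axes) encodes the absence of a medullary
#' cavity (MA = 0).
#'
#' @slot center ellipse centre (mm, length 2).
#' @slot semiAxes major/minor semi-axes (mm, length 2).
#' @slot orientationDeg angle of the first semi-axis from x, degrees.
#' @export
setClass("EndocortealEllipse",
  representation(center = "numeric", semiAxes = "numeric",
                 orientationDeg = "numeric"))

#' SectionGeometry: complete per-section measurement record
#'
#' All areas are mm^2, second moments of area (SMA) mm^4, angles degrees.
#' Ix is the SMA about the centroidal mediolateral axis (bending rigidity in
#' the anteroposterior plane), Iy about the anteroposterior axis.
#'
#' @slot TA total subperiosteal area.
#' @slot CA cortical area, TA - MA.
#' @slot MA medullary area (fitted-ellipse area).
#' @slot CPA cortical porosity area.
#' @slot Ix,Iy,Ixy centroidal SMAs about the ML/AP axes and product moment.
#' @slot Imax,Imin principal SMAs.
#' @slot thetaDeg angle of the Imax axis from x, in (-90, 90].
#' @slot imaxIminRatio Imax/Imin.
#' @slot ixIyRatio Ix/Iy.
#' @slot medullaryIndex MA/TA.
#' @slot porosityIndex CPA/CA.
#' @slot provenance specimen/section id.
#' @export
setClass("SectionGeometry",
  representation(TA = "numeric", CA = "numeric", MA = "numeric",
                 CPA = "numeric", Ix = "numeric", Iy = "numeric",
                 Ixy = "numeric", Imax = "numeric", Imin = "numeric",
                 thetaDeg = "numeric", imaxIminRatio = "numeric",
                 ixIyRatio = "numeric", medullaryIndex = "numeric",
                 porosityIndex = "numeric", provenance = "character"),
  prototype(provenance = NA_character_))

setValidity("SectionGeometry", function(object) {
  msg <- NULL
  if (abs(object@TA - (object@CA + object@MA)) > 1e-9 * max(object@TA, 1))
    msg <- c(msg, "TA must equal CA + MA")
  if (object@Imax + 1e-12 < object@Imin) msg <- c(msg, "Imax must be >= Imin")
  if (object@medullaryIndex < 0 || object@medullaryIndex > 1)
    msg <- c(msg, "medullaryIndex must lie in [0, 1]")
  if (object@porosityIndex < 0 || object@porosityIndex > 1)
    msg <- c(msg, "porosityIndex must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' GrowthCurve: cubic femur-length-on-age growth model
#'
#' FL(a) = c0 + c1 a + c2 a^2 + c3 a^3 with FL in mm and a in years.
#'
#' @slot coefficients named numeric c0..c3.
#' @slot ageRange observed age range (years) of the calibration data.
#' @slot lengthRange observed femur-length range (mm).
#' @slot monotone TRUE if FL is strictly increasing on ageRange (checked on
#'   a 1000-point grid).
#' @export
setClass("GrowthCurve",
  representation(coefficients = "numeric", ageRange = "numeric",
                 lengthRange = "numeric", monotone = "logical"))

setValidity("GrowthCurve", function(object) {
  msg <- NULL
  if (length(object@coefficients) != 4L)
    msg <- c(msg, "coefficients must have length 4 (c0..c3)")
  if (length(object@ageRange) != 2L || diff(object@ageRange) <= 0)
    msg <- c(msg, "ageRange must be an increasing pair")
  if (is.null(msg)) TRUE else msg
})

#' PhantomSpec: generative ground truth for a bone phantom volume
#'
#' Outer and inner cortical surfaces are elliptical cross-sections whose
#' semi-axes follow piecewise-linear profiles in the length fraction z
#' (0 = distal end). Profiles are 3-column matrices \code{(zFrac, a, b)} in mm
#' with a = ML semi-axis, b = AP semi-axis.
#'
#' @slot lengthMm physical intermetaphyseal length of the phantom.
#' @slot outerProfile piecewise-linear outer semi-axis profile.
#' @slot innerProfile piecewise-linear endocortical semi-axis profile (all
#'   values strictly below the outer profile; zeros = no cavity).
#' @slot poreFraction target intracortical pore area fraction per section,
#'   in [0, 0.4].
#' @slot poreRadiusMm mean planted pore radius (mm).
#' @slot tiltEulerDeg rotation (degrees about x, y, z) applied to the
#'   finished volume.
#' @slot voxelSizeMm isotropic voxel size (mm).
#' @slot backgroundIntensity,boneIntensity 8-bit grayscale levels
#'   (bone > background).
#' @slot noiseSd additive Gaussian grayscale noise, clipped to [0, 255].
#' @slot seed RNG seed making the phantom reproducible.
#' @export
setClass("PhantomSpec",
  representation(lengthMm = "numeric", outerProfile = "matrix",
                 innerProfile = "matrix", poreFraction = "numeric",
                 poreRadiusMm = "numeric", tiltEulerDeg = "numeric",
                 voxelSizeMm = "numeric", backgroundIntensity = "numeric",
                 boneIntensity = "numeric", noiseSd = "numeric",
                 seed = "numeric"))

setValidity("PhantomSpec", function(object) {
  msg <- NULL
  if (object@lengthMm <= 0) msg <- c(msg, "lengthMm must be positive")
  if (object@voxelSizeMm <= 0) msg <- c(msg, "voxelSizeMm must be positive")
  if (object@poreFraction < 0 || object@poreFraction > 0.4)
    msg <- c(msg, "poreFraction must lie in [0, 0.4]")
  if (object@boneIntensity <= object@backgroundIntensity)
    msg <- c(msg, "boneIntensity must exceed backgroundIntensity")
  zf <- seq(0, 1, length.out = 101)
  outer <- interpProfile(object@outerProfile, zf)
  inner <- interpProfile(object@innerProfile, zf)
  if (any(inner[, 1] >= outer[, 1]) || any(inner[, 2] >= outer[, 2]))
    msg <- c(msg, "inner semi-axes must be strictly below outer semi-axes")
  if (is.null(msg)) TRUE else msg
})

#' CohortSpec: generative ground truth for an ontogenetic cohort
#'
#' Trajectories give each individual's true section indices as smooth
#' functions of age; phantom parameters are derived from them. See
#' [medullaryTrajectory()], [porosityTrajectory()] and [shapeTrajectory()]
#' for the parameterisations and defaults.
#'
#' @slot nIndividuals number of individuals (>= 2).
#' @slot ageRangeYears sampling range for ages (uniform draw).
#' @slot medullaryTrajectory named numeric: adultLevel, infantExcess,
#'   excessTau, peakAge, riseAmplitude, fallSharpness.
#' @slot porosityTrajectory named numeric: initialLevel, declineRate,
#'   plateau.
#' @slot shapeTrajectory named numeric: initialRatio, adultRatio,
#'   declineRate (Ix/Iy).
#' @slot growthCurve [GrowthCurve-class] linking age to femur length.
#' @slot noiseSds named numeric: medullary (additive sd), porosityCv
#'   (lognormal cv), shape (additive sd), femurLength (mm sd).
#' @slot seed RNG seed.
#' @export
setClass("CohortSpec",
  representation(nIndividuals = "numeric", ageRangeYears = "numeric",
                 medullaryTrajectory = "numeric",
                 porosityTrajectory = "numeric",
                 shapeTrajectory = "numeric", growthCurve = "GrowthCurve",
                 noiseSds = "numeric", seed = "numeric"))

setValidity("CohortSpec", function(object) {
  msg <- NULL
  if (object@nIndividuals < 2) msg <- c(msg, "nIndividuals must be >= 2")
  if (length(object@ageRangeYears) != 2L || diff(object@ageRangeYears) <= 0)
    msg <- c(msg, "ageRangeYears must be an increasing pair")
  if (is.null(msg)) TRUE else msg
})

#' TrendFit: a LOESS ontogenetic trend curve
#'
#' @slot grid predictor grid (age, years) covering the observed range.
#' @slot fitted fitted values on the grid.
#' @slot halfWidth pointwise 95 percent interval half-widths.
#' @slot span LOESS span used.
#' @slot degree local polynomial degree used.
#' @slot n number of observations.
#' @export
setClass("TrendFit",
  representation(grid = "numeric", fitted = "numeric",
                 halfWidth = "numeric", span = "numeric", degree = "numeric",
                 n = "numeric"))
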