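#' Construct a PhantomSpec
#'
#' Defines a tapered elliptical-annulus bone phantom: outer and endocortical
#' surfaces are ellipses whose ML/AP semi-axes follow piecewise-linear
#' profiles along the length fraction (0 = distal end). The default profiles
#' give a flared distal metaphysis, a mid-shaft waist and a moderately flared
#' proximal end, so sections at 35/50/65 percent of length differ measurably,
#' and an ML-dominant distal section so automated in-plane orientation is
#' well defined.
#'
#' @param lengthMm phantom length in mm.
#' @param outerProfile,innerProfile 3-column matrices \code{(zFrac, a, b)} in
#'   mm (a = ML, b = AP semi-axis); the inner profile must lie strictly
#'   below the outer everywhere. An all-zero inner profile means no cavity.
#' @param poreFraction target intracortical pore area fraction per section
#'   (0 to 0.4).
#' @param poreRadiusMm mean planted pore radius in mm.
#' @param tiltEulerDeg rotation (deg about x, y, z) applied to the volume.
#' @param voxelSizeMm isotropic voxel size in mm.
#' @param backgroundIntensity,boneIntensity 8-bit grayscale levels.
#' @param noiseSd additive Gaussian grayscale noise sd.
#' @param seed RNG seed.
#' @return a validated [PhantomSpec-class].
#' @export
phantomSpec <- function(lengthMm = 60,
                        outerProfile = cbind(zFrac = c(0, 0.45, 1),
                                             a = c(9, 6.5, 8),
                                             b = c(6.5, 5, 6)),
                        innerProfile = cbind(zFrac = c(0, 0.45, 1),
                                             a = c(5, 3.2, 4.2),
                                             b = c(3.8, 2.5, 3.4)),
                        poreFraction = 0, poreRadiusMm = 0.25,
                        tiltEulerDeg = c(0, 0, 0), voxelSizeMm = 0.25,
                        backgroundIntensity = 20, boneIntensity = 200,
                        noiseSd = 0, seed = 1L) {
  new("PhantomSpec", lengthMm = lengthMm, outerProfile = outerProfile,
      innerProfile = innerProfile, poreFraction = poreFraction,
      poreRadiusMm = poreRadiusMm, tiltEulerDeg = tiltEulerDeg,
      voxelSizeMm = voxelSizeMm, backgroundIntensity = backgroundIntensity,
      boneIntensity = boneIntensity, noiseSd = noiseSd, seed = seed)
}

#' Closed-form section truth for an elliptical annulus
#'
#' Areas and second moments of the pore-free annulus with outer semi-axes
#' (a, b) and inner semi-axes (ai, bi): TA = pi a b, MA = pi ai bi,
#' Ix = pi (a b^3 - ai bi^3) / 4, Iy = pi (a^3 b - ai^3 bi) / 4. Planted pore
#' area enters CPA and the porosity index only (truth second moments ignore
#' pores by design; at <= 10 percent porosity their perturbation is below
#' the pipeline's tolerance).
#'
#' @param outer,inner numeric length-2: (a, b) and (ai, bi) in mm.
#' @param poreFraction planted pore area fraction of the cortex.
#' @return named numeric vector of all truth fields (areas mm^2, SMA mm^4).
#' @examples
#' annulusTruth(c(10, 10), c(5, 5))  # circular annulus: medullary index 0.25
#' @export
annulusTruth <- function(outer, inner = c(0, 0), poreFraction = 0) {
  a <- outer[1]; b <- outer[2]; ai <- inner[1]; bi <- inner[2]
  TA <- pi * a * b
  MA <- pi * ai * bi
  CA <- TA - MA
  CPA <- poreFraction * CA
  Ix <- pi * (a * b^3 - ai * bi^3) / 4
  Iy <- pi * (a^3 * b - ai^3 * bi) / 4
  c(TA_mm2 = TA, CA_mm2 = CA, MA_mm2 = MA, CPA_mm2 = CPA,
    Ix_mm4 = Ix, Iy_mm4 = Iy, Imax_mm4 = max(Ix, Iy),
    Imin_mm4 = min(Ix, Iy), imax_imin_ratio = max(Ix, Iy) / min(Ix, Iy),
    ix_iy_ratio = Ix / Iy, medullary_index = MA / TA,
    porosity_index = if (CA > 0) CPA / CA else 0)
}

#' Section truth of a phantom at a length fraction
#'
#' @param spec a [PhantomSpec-class].
#' @param fraction length fraction from the distal end, in (0, 1).
#' @return named numeric truth vector (see [annulusTruth()]).
#' @export
sectionTruthAt <- function(spec, fraction) {
  outer <- interpProfile(spec@outerProfile, fraction)
  inner <- interpProfile(spec@innerProfile, fraction)
  annulusTruth(c(outer[1, 1], outer[1, 2]), c(inner[1, 1], inner[1, 2]),
               spec@poreFraction)
}

## Plant non-overlapping circular pores wholly interior to the cortical
## annulus until the planted area fraction of the cortex is within tol of
## `fraction`. Returns a matrix (cx, cy, r) in mm. Errors if packing is
## infeasible.
plantPores <- function(outer, inner, fraction, meanRadius, minRadius,
                       tol = 0.005, maxAttempts = 20000L) {
  if (fraction <= 0) return(matrix(numeric(0), 0, 3))
  a <- outer[1]; b <- outer[2]; ai <- inner[1]; bi <- inner[2]
  cortexArea <- pi * (a * b - ai * bi)
  thickness <- if (ai > 0) min(a - ai, b - bi) else min(a, b)
  if (2 * meanRadius >= 0.9 * thickness)
    stop("infeasible pore packing: pore diameter ~ cortical thickness")
  target <- fraction * cortexArea
  phi <- seq(0, 2 * pi, length.out = 25)[-25]
  ## keep a raster-safe margin to both borders so pores never breach the
  ## periosteal or endocortical surface after pixelisation
  mar <- minRadius
  insideCortex <- function(cx, cy, r) {
    bx <- cx + r * cos(phi); by <- cy + r * sin(phi)
    if (any((bx / (a - mar))^2 + (by / (b - mar))^2 >= 1)) return(FALSE)
    if (ai > 0 && any((bx / (ai + mar))^2 + (by / (bi + mar))^2 <= 1))
      return(FALSE)
    TRUE
  }
  pores <- matrix(numeric(0), 0, 3)
  planted <- 0
  attempts <- 0L
  while (target - planted > tol * cortexArea / 2) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      stop("infeasible pore packing: attempt budget exhausted at ",
           sprintf("%.1f%% of target", 100 * planted / target))
    r <- stats::rnorm(1, meanRadius, 0.2 * meanRadius)
    r <- min(max(r, 0.6 * meanRadius), 1.5 * meanRadius)
    remaining <- target - planted
    if (pi * r^2 > remaining) r <- max(sqrt(remaining / pi), minRadius)
    theta <- stats::runif(1, 0, 2 * pi)
    t <- stats::runif(1)
    x0 <- ai * cos(theta); y0 <- bi * sin(theta)
    x1 <- a * cos(theta); y1 <- b * sin(theta)
    cx <- x0 + t * (x1 - x0); cy <- y0 + t * (y1 - y0)
    if (!insideCortex(cx, cy, r)) next
    if (nrow(pores) &&
        any(sqrt((pores[, 1] - cx)^2 + (pores[, 2] - cy)^2) <
            pores[, 3] + r + minRadius / 2)) next
    pores <- rbind(pores, c(cx, cy, r))
    planted <- planted + pi * r^2
  }
  if (abs(planted / cortexArea - fraction) > tol)
    stop("infeasible pore packing: planted fraction misses target tolerance")
  pores
}

## Rasterize one annulus slice (pixel-centre test) centred in an nx x ny
## grid. Returns logical bone mask.
rasterizeAnnulus <- function(nx, ny, px, outerAxes, innerAxes, pores) {
  x <- (seq_len(nx) - (nx + 1) / 2) * px
  y <- (seq_len(ny) - (ny + 1) / 2) * px
  X <- outer(x, rep(1, ny)); Y <- outer(rep(1, nx), y)
  bone <- (X / outerAxes[1])^2 + (Y / outerAxes[2])^2 <= 1
  if (innerAxes[1] > 0)
    bone <- bone & ((X / innerAxes[1])^2 + (Y / innerAxes[2])^2 > 1)
  if (nrow(pores))
    for (k in seq_len(nrow(pores)))
      bone <- bone & ((X - pores[k, 1])^2 + (Y - pores[k, 2])^2 >
                        pores[k, 3]^2)
  bone
}

#' Generate a single 2D cross-section phantom with exact truth
#'
#' 2D analogue of [makePhantomVolume()] for fast unit-level validation: one
#' elliptical annulus with optional planted pores and optional endocortical
#' scalloping, rasterized at pixel centres, plus the closed-form truth.
#'
#' @param outerSemiAxes,innerSemiAxes numeric length-2 (a, b) in mm; inner
#'   \code{c(0, 0)} means no medullary cavity.
#' @param poreFraction target pore area fraction of the cortex.
#' @param pixelSize pixel size in mm.
#' @param poreRadiusMm mean pore radius in mm.
#' @param rotationDeg optional in-plane rotation of the section (applied
#'   analytically to the ellipse/pore geometry, not by resampling).
#' @param scallopPores number of semicircular notches planted on the
#'   endocortical border (merged with the cavity), emulating resorption
#'   scalloping; truth MA is left at the unscalloped ellipse.
#' @param backgroundIntensity,boneIntensity,noiseSd grayscale model.
#' @param seed RNG seed.
#' @return list with \code{section} (a [CrossSectionImage-class]),
#'   \code{truth} (named numeric, see [annulusTruth()]), and
#'   \code{plantedPoreArea} (mm^2).
#' @export
makeSectionPhantom <- function(outerSemiAxes, innerSemiAxes = c(0, 0),
                               poreFraction = 0, pixelSize = 0.05,
                               poreRadiusMm = 0.25, rotationDeg = 0,
                               scallopPores = 0L,
                               backgroundIntensity = 20, boneIntensity = 200,
                               noiseSd = 0, seed = 1L) {
  stopifnot(all(innerSemiAxes < outerSemiAxes) || all(innerSemiAxes == 0))
  if (poreFraction < 0 || poreFraction > 0.4)
    stop("poreFraction must lie in [0, 0.4]")
  set.seed(seed)
  a <- outerSemiAxes[1]; b <- outerSemiAxes[2]
  px <- pixelSize
  pores <- plantPores(outerSemiAxes, innerSemiAxes, poreFraction,
                      poreRadiusMm, minRadius = 1.5 * px)
  scallops <- matrix(numeric(0), 0, 3)
  if (scallopPores > 0 && innerSemiAxes[1] > 0) {
    th <- stats::runif(scallopPores, 0, 2 * pi)
    rs <- 0.1 * min(innerSemiAxes) *
      stats::runif(scallopPores, 0.7, 1.3)
    scallops <- cbind(innerSemiAxes[1] * cos(th), innerSemiAxes[2] * sin(th),
                      rs)
  }
  allPores <- rbind(pores, scallops)
  half <- max(a, b) * 1.15 + 4 * px
  n <- 2L * ceiling(half / px) + 1L
  if (rotationDeg != 0) {
    ## rotate geometry analytically: rasterize in rotated coordinates
    t0 <- rotationDeg * pi / 180
    x <- (seq_len(n) - (n + 1) / 2) * px
    X <- outer(x, rep(1, n)); Y <- outer(rep(1, n), x)
    U <- X * cos(t0) + Y * sin(t0)
    V <- -X * sin(t0) + Y * cos(t0)
    bone <- (U / a)^2 + (V / b)^2 <= 1
    if (innerSemiAxes[1] > 0)
      bone <- bone & ((U / innerSemiAxes[1])^2 + (V / innerSemiAxes[2])^2 > 1)
    if (nrow(allPores))
      for (k in seq_len(nrow(allPores)))
        bone <- bone & ((U - allPores[k, 1])^2 + (V - allPores[k, 2])^2 >
                          allPores[k, 3]^2)
  } else {
    bone <- rasterizeAnnulus(n, n, px, outerSemiAxes, innerSemiAxes, allPores)
  }
  img <- matrix(backgroundIntensity, n, n)
  img[bone] <- boneIntensity
  if (noiseSd > 0)
    img <- pmin(pmax(img + stats::rnorm(length(img), 0, noiseSd), 0), 255)
  img <- round(img)
  truth <- annulusTruth(outerSemiAxes, innerSemiAxes, poreFraction)
  if (nrow(pores)) {  # exact planted CPA (scallops belong to the cavity)
    plantedArea <- sum(pi * pores[, 3]^2)
    truth["CPA_mm2"] <- plantedArea
    truth["porosity_index"] <- plantedArea / truth[["CA_mm2"]]
  }
  list(section = new("CrossSectionImage", intensities = img, pixelSize = px,
                     provenance = sprintf("phantom2d_seed%d", seed)),
       truth = truth,
       plantedPoreArea = if (nrow(pores)) sum(pi * pores[, 3]^2) else 0)
}

#' Generate a 3D bone phantom volume with per-slice truth
#'
#' Rasterizes the tapered elliptical annulus described by a
#' [PhantomSpec-class] slice by slice (planting pores independently per
#' slice), pads with background, applies the specified tilt by
#' nearest-neighbour resampling, and adds clipped Gaussian grayscale noise.
#' Truth at any length fraction comes from the continuous closed forms via
#' [sectionTruthAt()].
#'
#' @param spec a [PhantomSpec-class].
#' @param truthFractions length fractions at which to tabulate truth
#'   (default c(0.35, 0.5, 0.65)).
#' @return list with \code{volume} (a [VoxelVolume-class]), \code{truth}
#'   (data frame, one row per requested fraction), \code{boneVoxelCount}
#'   (pre-tilt planted bone voxels), and \code{spec}.
#' @export
makePhantomVolume <- function(spec, truthFractions = c(0.35, 0.5, 0.65)) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  set.seed(spec@seed)
  px <- spec@voxelSizeMm
  nz <- max(3L, round(spec@lengthMm / px))
  maxA <- max(spec@outerProfile[, 2]); maxB <- max(spec@outerProfile[, 3])
  nx <- 2L * ceiling((maxA * 1.1 + 3 * px) / px) + 1L
  ny <- 2L * ceiling((maxB * 1.1 + 3 * px) / px) + 1L
  pad <- 3L
  vol <- array(spec@backgroundIntensity, c(nx, ny, nz + 2L * pad))
  boneCount <- 0
  for (k in seq_len(nz)) {
    zf <- (k - 0.5) / nz
    outer <- interpProfile(spec@outerProfile, zf)[1, ]
    inner <- interpProfile(spec@innerProfile, zf)[1, ]
    pores <- plantPores(outer, inner, spec@poreFraction, spec@poreRadiusMm,
                        minRadius = 1.5 * px)
    bone <- rasterizeAnnulus(nx, ny, px, outer, inner, pores)
    boneCount <- boneCount + sum(bone)
    slice <- matrix(spec@backgroundIntensity, nx, ny)
    slice[bone] <- spec@boneIntensity
    vol[, , k + pad] <- slice
  }
  if (any(spec@tiltEulerDeg != 0)) {
    R <- eulerRotation(spec@tiltEulerDeg)
    vol <- rotateVolumeNN(vol, R, spec@backgroundIntensity)
  }
  if (spec@noiseSd > 0)
    vol <- pmin(pmax(vol + stats::rnorm(length(vol), 0, spec@noiseSd), 0), 255)
  vol <- round(vol)
  truth <- do.call(rbind, lapply(truthFractions, function(f)
    data.frame(fraction = f, t(sectionTruthAt(spec, f)))))
  list(volume = new("VoxelVolume", intensities = vol, voxelSize = px,
                    provenance = sprintf("phantom3d_seed%d", spec@seed)),
       truth = truth, boneVoxelCount = boneCount, spec = spec)
}

## Nearest-neighbour rotation of a 3D array about its centre. R maps input
## coordinates to output coordinates; the output grid covers the rotated
## bounding box.
rotateVolumeNN <- function(vol, R, padValue) {
  d <- dim(vol)
  half <- d / 2
  corners <- as.matrix(expand.grid(c(-1, 1) * half[1], c(-1, 1) * half[2],
                                   c(-1, 1) * half[3]))
  rot <- corners %*% t(R)
  dOut <- ceiling(apply(rot, 2, function(v) max(abs(v))) * 2) + 1L
  out <- array(padValue, dOut)
  ## output voxel centres (index units, centred); work slice-by-slice in z
  ## to keep memory flat: in = t(R) %*% out, so source coordinates are
  ## x-term + y-term + z-term with the xy part shared across slices
  xo <- seq_len(dOut[1]) - (dOut[1] + 1) / 2
  yo <- seq_len(dOut[2]) - (dOut[2] + 1) / 2
  zo <- seq_len(dOut[3]) - (dOut[3] + 1) / 2
  XYx <- outer(xo * R[1, 1], yo * R[2, 1], "+") + (d[1] + 1) / 2
  XYy <- outer(xo * R[1, 2], yo * R[2, 2], "+") + (d[2] + 1) / 2
  XYz <- outer(xo * R[1, 3], yo * R[2, 3], "+") + (d[3] + 1) / 2
  nxyIn <- d[1] * d[2]
  for (k in seq_len(dOut[3])) {
    ## round half up: banker's rounding on the exact half-integer offsets of
    ## near-identity rotations would duplicate/drop alternating pixels
    ix <- floor(XYx + zo[k] * R[3, 1] + 0.5)
    iy <- floor(XYy + zo[k] * R[3, 2] + 0.5)
    iz <- floor(XYz + zo[k] * R[3, 3] + 0.5)
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] &
      iz >= 1 & iz <= d[3]
    if (!any(ok)) next
    idx <- (iz[ok] - 1) * nxyIn + (iy[ok] - 1) * d[1] + ix[ok]
    slice <- matrix(padValue, dOut[1], dOut[2])
    slice[ok] <- vol[idx]
    out[, , k] <- slice
  }
  out
}

## In-plane (about z) nearest-neighbour rotation applied slice-wise with one
## precomputed 2D index map; much cheaper than the general 3D path.
rotateVolumeAboutZ <- function(vol, angleDeg, padValue) {
  d <- dim(vol)
  t0 <- angleDeg * pi / 180
  xo <- seq_len(d[1]) - (d[1] + 1) / 2
  yo <- seq_len(d[2]) - (d[2] + 1) / 2
  ix <- floor(outer(xo * cos(t0), yo * sin(t0), "+") + (d[1] + 1) / 2 + 0.5)
  iy <- floor(outer(-xo * sin(t0), yo * cos(t0), "+") + (d[2] + 1) / 2 + 0.5)
  ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2]
  idx <- (iy - 1) * d[1] + ix
  idx[!ok] <- NA_integer_
  out <- array(padValue, d)
  for (k in seq_len(d[3])) {
    sl <- vol[, , k][idx]
    sl[is.na(sl)] <- padValue
    out[, , k] <- sl
  }
  out
}
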