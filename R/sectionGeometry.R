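#' Trace the periosteal (subperiosteal) contour of a cross-section
#'
#' Thresholds the section, keeps the largest 8-connected foreground
#' component, fills interior holes (medullary cavity and pores), and traces
#' the outer boundary. The enclosed area is the filled pixel count times the
#' pixel area; the polygon (iso-contour at half foreground level) is carried
#' for reporting and plotting.
#'
#' @param section a [CrossSectionImage-class].
#' @param threshold intensity threshold; pixels strictly above are bone.
#' @return a [PeriostealContour-class].
#' @export
periostealContour <- function(section, threshold) {
  stopifnot(is(section, "CrossSectionImage"))
  img <- section@intensities
  px <- section@pixelSize
  mask <- img > threshold
  if (!any(mask)) stop("empty foreground: nothing above threshold")
  comp <- largestComponent(mask, 8L)
  filled <- fillHoles(comp)
  area <- sum(filled) * px^2

  nx <- nrow(filled); ny <- ncol(filled)
  zpad <- matrix(0, nx + 2L, ny + 2L)
  zpad[2:(nx + 1L), 2:(ny + 1L)] <- filled
  xs <- (seq_len(nx + 2L) - 1.5) * px  # padded pixel centres
  ys <- (seq_len(ny + 2L) - 1.5) * px
  cl <- grDevices::contourLines(xs, ys, zpad, levels = 0.5)
  if (!length(cl)) stop("contour tracing failed")
  areas <- vapply(cl, function(ct) polygonArea(cbind(ct$x, ct$y)), 0)
  best <- cl[[which.max(areas)]]
  poly <- cbind(x = best$x, y = best$y)
  if (any(poly[1, ] != poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  new("PeriostealContour", polygon = poly, enclosedArea = area)
}

## filled subperiosteal mask used by the downstream steps
periostealMask <- function(section, threshold) {
  mask <- section@intensities > threshold
  if (!any(mask)) stop("empty foreground: nothing above threshold")
  fillHoles(largestComponent(mask, 8L))
}

#' Fit the endocortical ellipse of a cross-section
#'
#' Identifies the medullary cavity as the largest non-bone connected region
#' enclosed by the periosteal outline and fits an ellipse to its boundary
#' pixels by direct least-squares conic fitting, with a half-pixel outward
#' correction (boundary pixel centres sit half a pixel inside the true
#' border). Degenerate fits fall back to the cavity's moment-equivalent
#' ellipse. A section without an enclosed cavity yields a zero-area ellipse
#' (with a warning), encoding MA = 0.
#'
#' @param section a [CrossSectionImage-class].
#' @param contour the [PeriostealContour-class] (used for reporting only; the
#'   enclosed region is recomputed from the threshold).
#' @param threshold intensity threshold; pixels strictly above are bone.
#' @return an [EndocortealEllipse-class].
#' @export
endocorticalEllipse <- function(section, contour, threshold) {
  filled <- periostealMask(section, threshold)
  bone <- section@intensities > threshold
  px <- section@pixelSize
  cavityInfo <- medullaryComponent(filled, bone)
  if (is.null(cavityInfo)) {
    warning("no enclosed medullary cavity: returning degenerate ellipse (MA = 0)")
    return(new("EndocortealEllipse", center = c(NA_real_, NA_real_),
               semiAxes = c(0, 0), orientationDeg = 0))
  }
  cav <- cavityInfo$mask
  ## boundary pixels: cavity pixels with a 4-neighbour outside the cavity
  nx <- nrow(cav); ny <- ncol(cav)
  shift <- function(m, dx, dy) {
    out <- matrix(FALSE, nx, ny)
    xs <- seq_len(nx) + dx; ys <- seq_len(ny) + dy
    okx <- xs >= 1 & xs <= nx; oky <- ys >= 1 & ys <= ny
    out[okx, oky] <- m[xs[okx], ys[oky]]
    out
  }
  interior <- shift(cav, 1, 0) & shift(cav, -1, 0) &
    shift(cav, 0, 1) & shift(cav, 0, -1)
  bpix <- which(cav & !interior, arr.ind = TRUE)
  pts <- cbind((bpix[, 1] - 0.5) * px, (bpix[, 2] - 0.5) * px)
  fit <- if (nrow(pts) >= 6L) fitEllipseDirect(pts) else NULL
  if (!is.null(fit)) {
    ## reject wild fits (centre outside cavity bbox or area far from the
    ## cavity's pixel area)
    cavArea <- sum(cav) * px^2
    fitArea <- pi * prod(fit$semiAxes + px / 2)
    bb <- apply(pts, 2, range)
    if (fit$center[1] < bb[1, 1] || fit$center[1] > bb[2, 1] ||
        fit$center[2] < bb[1, 2] || fit$center[2] > bb[2, 2] ||
        fitArea > 1.8 * cavArea || fitArea < 0.4 * cavArea)
      fit <- NULL
  }
  if (is.null(fit)) fit <- momentEllipse(cav, px)
  if (is.null(fit)) {
    warning("cavity too small to fit: returning degenerate ellipse (MA = 0)")
    return(new("EndocortealEllipse", center = c(NA_real_, NA_real_),
               semiAxes = c(0, 0), orientationDeg = 0))
  }
  new("EndocortealEllipse", center = fit$center,
      semiAxes = fit$semiAxes + px / 2, orientationDeg = fit$orientationDeg)
}

## Largest non-bone 4-connected region strictly inside the filled outline;
## NULL if no enclosed cavity exists. Also returns the component's label
## image so porosity can exclude cavity spill-over.
medullaryComponent <- function(filled, bone) {
  inside <- filled & !bone
  if (!any(inside)) return(NULL)
  lab <- labelComponents(inside, 4L)
  sizes <- tabulate(lab[lab > 0L])
  if (!length(sizes)) return(NULL)
  keep <- which.max(sizes)
  list(mask = lab == keep, labels = lab, cavityLabel = keep)
}

#' Compute total, medullary and cortical areas
#'
#' TA is the area enclosed by the periosteal outline, MA the fitted-ellipse
#' area (pi a b), and CA = TA - MA, so TA = CA + MA holds exactly.
#'
#' @param contour a [PeriostealContour-class].
#' @param ellipse an [EndocortealEllipse-class] (possibly degenerate).
#' @return named numeric: TA, MA, CA (mm^2).
#' @export
computeAreas <- function(contour, ellipse) {
  TA <- contour@enclosedArea
  MA <- pi * prod(ellipse@semiAxes)
  if (MA >= TA) stop("ellipse fit escaped the cortex: MA >= TA")
  c(TA = TA, MA = MA, CA = TA - MA)
}

#' Centroidal second moments of area of the cortical region
#'
#' The region is the bone area between the periosteal outline and the
#' endocortical ellipse treated as solid (pores filled), mirroring
#' outline-based quantification. Moments are computed by pixel summation:
#' Ix = sum (y - ybar)^2 A_px, Iy = sum (x - xbar)^2 A_px,
#' Ixy = sum (x - xbar)(y - ybar) A_px. Principal values are
#' (Ix+Iy)/2 +/- sqrt(((Ix-Iy)/2)^2 + Ixy^2) and theta is the angle of the
#' Imax axis from x (ML), mapped to (-90, 90].
#'
#' @param region logical matrix of the solid cortical region.
#' @param px pixel size in mm.
#' @return named numeric: Ix, Iy, Ixy, Imax, Imin, thetaDeg.
#' @export
secondMoments <- function(region, px) {
  idx <- which(region, arr.ind = TRUE)
  if (nrow(idx) < 2L) stop("region degenerate: fewer than two pixels")
  x <- (idx[, 1] - 0.5) * px
  y <- (idx[, 2] - 0.5) * px
  A <- px^2
  xb <- mean(x); yb <- mean(y)
  Ix <- sum((y - yb)^2) * A
  Iy <- sum((x - xb)^2) * A
  Ixy <- sum((x - xb) * (y - yb)) * A
  half <- sqrt(((Ix - Iy) / 2)^2 + Ixy^2)
  Imax <- (Ix + Iy) / 2 + half
  Imin <- (Ix + Iy) / 2 - half
  theta <- 0.5 * atan2(2 * Ixy, Iy - Ix) * 180 / pi
  if (theta <= -90) theta <- theta + 180
  if (theta > 90) theta <- theta - 180
  c(Ix = Ix, Iy = Iy, Ixy = Ixy, Imax = Imax, Imin = Imin, thetaDeg = theta)
}

#' Cortical porosity area of a cross-section
#'
#' Counts sub-threshold pixels between the periosteal outline and the
#' endocortical ellipse. Pixels belonging to the medullary cavity's own
#' connected component are excluded: where the fitted ellipse slightly
#' under-covers the cavity, that spill-over is medullary space, not
#' intracortical porosity.
#'
#' @inheritParams endocorticalEllipse
#' @param ellipse the fitted [EndocortealEllipse-class].
#' @return CPA in mm^2.
#' @export
corticalPorosity <- function(section, contour, ellipse, threshold) {
  filled <- periostealMask(section, threshold)
  bone <- section@intensities > threshold
  px <- section@pixelSize
  inEllipse <- if (all(ellipse@semiAxes > 0))
    insideEllipseMask(nrow(filled), ncol(filled), px, ellipse@center,
                      ellipse@semiAxes, ellipse@orientationDeg)
  else matrix(FALSE, nrow(filled), ncol(filled))
  cortex <- filled & !inEllipse
  pores <- cortex & !bone
  cavityInfo <- medullaryComponent(filled, bone)
  if (!is.null(cavityInfo)) pores <- pores & !cavityInfo$mask
  sum(pores) * px^2
}

#' Quantify one cross-section end-to-end
#'
#' Runs threshold, periosteal contour, endocortical ellipse, areas, second
#' moments and porosity on a single section, returning the complete
#' [SectionGeometry-class] record. Deterministic for fixed input and
#' configuration.
#'
#' @param section a [CrossSectionImage-class].
#' @param threshold \code{"auto"} (default; minimum threshold of the section
#'   histogram) or an explicit intensity.
#' @return a [SectionGeometry-class].
#' @examples
#' ph <- makeSectionPhantom(outerSemiAxes = c(10, 5), innerSemiAxes = c(6, 3),
#'                          poreFraction = 0, pixelSize = 0.05, seed = 1)
#' sectionGeometry(ph$section)
#' @export
sectionGeometry <- function(section, threshold = "auto") {
  stopifnot(is(section, "CrossSectionImage"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  thr <- if (identical(threshold, "auto"))
    stage("threshold", minimumThreshold(intensityHistogram(section@intensities)))
  else threshold
  contour <- stage("contour", periostealContour(section, thr))
  ellipse <- stage("ellipse", endocorticalEllipse(section, contour, thr))
  areas <- stage("areas", computeAreas(contour, ellipse))
  px <- section@pixelSize
  filled <- periostealMask(section, thr)
  inEllipse <- if (all(ellipse@semiAxes > 0))
    insideEllipseMask(nrow(filled), ncol(filled), px, ellipse@center,
                      ellipse@semiAxes, ellipse@orientationDeg)
  else matrix(FALSE, nrow(filled), ncol(filled))
  mom <- stage("moments", secondMoments(filled & !inEllipse, px))
  CPA <- stage("porosity", corticalPorosity(section, contour, ellipse, thr))
  new("SectionGeometry",
      TA = unname(areas["TA"]), CA = unname(areas["CA"]),
      MA = unname(areas["MA"]), CPA = CPA,
      Ix = unname(mom["Ix"]), Iy = unname(mom["Iy"]),
      Ixy = unname(mom["Ixy"]), Imax = unname(mom["Imax"]),
      Imin = unname(mom["Imin"]), thetaDeg = unname(mom["thetaDeg"]),
      imaxIminRatio = unname(mom["Imax"] / mom["Imin"]),
      ixIyRatio = unname(mom["Ix"] / mom["Iy"]),
      medullaryIndex = unname(areas["MA"] / areas["TA"]),
      porosityIndex = unname(CPA / areas["CA"]),
      provenance = section@provenance)
}
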