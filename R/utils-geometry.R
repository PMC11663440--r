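## Internal geometry and labelling helpers shared across modules.

#' @useDynLib boneCSG, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Piecewise-linear interpolation of a (zFrac, a, b) profile matrix.
interpProfile <- function(profile, zFrac) {
  stopifnot(ncol(profile) == 3L)
  ord <- order(profile[, 1])
  a <- stats::approx(profile[ord, 1], profile[ord, 2], xout = zFrac,
                     rule = 2)$y
  b <- stats::approx(profile[ord, 1], profile[ord, 3], xout = zFrac,
                     rule = 2)$y
  cbind(a = a, b = b)
}

## round-half-away-from-zero (base round() is banker's rounding)
roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

## 3x3 rotation matrices, angles in degrees
rotX <- function(deg) {
  t <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
}
rotY <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
}
rotZ <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}
eulerRotation <- function(degXYZ) {
  rotZ(degXYZ[3]) %*% rotY(degXYZ[2]) %*% rotX(degXYZ[1])
}

## Connected-component labelling. mask: logical array (2D or 3D).
## connectivity: 4/8 for 2D, 6/26 for 3D.
labelComponents <- function(mask, connectivity) {
  d <- dim(mask)
  if (length(d) == 2L) {
    connectivity <- switch(as.character(connectivity),
                           "4" = 6L, "8" = 26L,
                           stop("2D connectivity must be 4 or 8"))
    d3 <- c(d, 1L)
  } else {
    if (!connectivity %in% c(6L, 26L))
      stop("3D connectivity must be 6 or 26")
    d3 <- d
  }
  lab <- cc_label(as.logical(mask), as.integer(d3), as.integer(connectivity))
  dim(lab) <- d
  lab
}

## Keep only the largest connected foreground component.
largestComponent <- function(mask, connectivity) {
  lab <- labelComponents(mask, connectivity)
  if (max(lab) == 0L) stop("empty foreground: no component to keep")
  keep <- which.max(tabulate(lab[lab > 0L]))
  lab == keep
}

## Fill interior holes of a 2D mask: background components (4-connected)
## not touching the image border are interior and get filled.
fillHoles <- function(mask) {
  bg <- labelComponents(!mask, 4L)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0L]
  filled <- mask | !(bg %in% c(0L, border))
  dim(filled) <- dim(mask)
  filled
}

## Pixel-centre coordinates (mm) for a matrix of dim c(nx, ny):
## x_i = (i - 0.5) * px, i = 1..nx (0-based physical origin at the corner).
pixelCenters <- function(n, px) (seq_len(n) - 0.5) * px

## Logical matrix: pixel centres inside an (optionally rotated) ellipse.
insideEllipseMask <- function(nx, ny, px, center, semiAxes, orientationDeg) {
  if (any(semiAxes <= 0)) return(matrix(FALSE, nx, ny))
  x <- pixelCenters(nx, px) - center[1]
  y <- pixelCenters(ny, px) - center[2]
  t <- orientationDeg * pi / 180
  X <- outer(x, rep(1, ny)); Y <- outer(rep(1, nx), y)
  u <- X * cos(t) + Y * sin(t)
  v <- -X * sin(t) + Y * cos(t)
  (u / semiAxes[1])^2 + (v / semiAxes[2])^2 <= 1
}

## Direct least-squares ellipse fit (Halir & Flusser's numerically stable
## formulation of the Fitzgibbon method). pts: 2-column matrix. Returns
## list(center, semiAxes, orientationDeg) or NULL if the fit degenerates.
fitEllipseDirect <- function(pts) {
  x <- pts[, 1] - mean(pts[, 1])
  y <- pts[, 2] - mean(pts[, 2])
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T1)) return(NULL)
  M <- S1 + S2 %*% T1
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok)) return(NULL)
  a1 <- evec[, ok[1]]
  par <- c(a1, T1 %*% a1)  # A B C D E F of A x^2 + B xy + C y^2 + D x + E y + F
  A <- par[1]; B <- par[2]; C <- par[3]; D <- par[4]; E <- par[5]; F <- par[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) return(NULL)
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  ## centred conic u' M u = -Fc; semi-axes from the eigen-decomposition of M
  M2 <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  ev2 <- eigen(M2, symmetric = TRUE)
  r2 <- -Fc / ev2$values
  if (any(!is.finite(r2)) || any(r2 <= 0)) return(NULL)
  list(center = c(cx + mean(pts[, 1]), cy + mean(pts[, 2])),
       semiAxes = sqrt(r2),
       orientationDeg = atan2(ev2$vectors[2, 1], ev2$vectors[1, 1]) * 180 / pi)
}

## Moment-equivalent ellipse of a logical region (pixel centres, mm):
## semi-axes 2*sqrt(eigenvalues of the covariance).
momentEllipse <- function(mask, px) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 2L) return(NULL)
  xy <- cbind((idx[, 1] - 0.5) * px, (idx[, 2] - 0.5) * px)
  ctr <- colMeans(xy)
  cv <- stats::cov(sweep(xy, 2, ctr))
  ev <- eigen(cv, symmetric = TRUE)
  if (any(ev$values <= 0)) return(NULL)
  list(center = ctr, semiAxes = 2 * sqrt(ev$values),
       orientationDeg = atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi)
}

## shoelace area of a closed polygon (2-column matrix)
polygonArea <- function(p) {
  n <- nrow(p)
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
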