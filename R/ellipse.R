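# Ellipse reconstruction: mirror completion of the visible arc, algebraic
# ellipse fitting on the conic form, and pixel-unit measurements.
#
# Pixel coordinate convention used throughout: x = column, y = row, both
# 0-based, origin at the top-left corner, y increasing downward.

## ---- conic <-> geometric parameter conversion -------------------------------

# conic coefficients c(A,B,C,D,E,F) of A x^2 + B xy + C y^2 + D x + E y + F = 0
# represented as the symmetric 3x3 matrix [[A, B/2, D/2], [B/2, C, E/2], [D/2, E/2, F]]
conic_to_matrix <- function(coefs) {
  matrix(c(coefs[1], coefs[2] / 2, coefs[4] / 2,
           coefs[2] / 2, coefs[3], coefs[5] / 2,
           coefs[4] / 2, coefs[5] / 2, coefs[6]), 3, 3)
}

matrix_to_conic <- function(M) {
  c(M[1, 1], 2 * M[1, 2], M[2, 2], 2 * M[1, 3], 2 * M[2, 3], M[3, 3])
}

# Recover center, semi-axes and tilt from conic coefficients.
# Returns NULL when the conic is not a real ellipse.
conic_to_geometry <- function(coefs) {
  A <- coefs[1]; B <- coefs[2]; C <- coefs[3]
  D <- coefs[4]; E <- coefs[5]; F <- coefs[6]
  disc <- B^2 - 4 * A * C
  if (!is.finite(disc) || disc >= 0) return(NULL)
  ctr <- tryCatch(solve(matrix(c(2 * A, B, B, 2 * C), 2, 2), c(-D, -E)),
                  error = function(e) NULL)
  if (is.null(ctr)) return(NULL)
  cx <- ctr[1]; cy <- ctr[2]
  F0 <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  theta <- 0.5 * atan2(B, A - C)
  ct <- cos(theta); st <- sin(theta)
  Ar <- A * ct^2 + B * ct * st + C * st^2   # coefficient along rotated x'
  Cr <- A * st^2 - B * ct * st + C * ct^2   # coefficient along rotated y'
  ax2 <- -F0 / Ar
  ay2 <- -F0 / Cr
  if (!is.finite(ax2) || !is.finite(ay2) || ax2 <= 0 || ay2 <= 0) return(NULL)
  ax <- sqrt(ax2); ay <- sqrt(ay2)
  if (ax >= ay) {
    semi_major <- ax; semi_minor <- ay; tilt <- theta
  } else {
    semi_major <- ay; semi_minor <- ax; tilt <- theta + pi / 2
  }
  # normalize tilt to (-pi/2, pi/2]
  tilt <- tilt - pi * floor((tilt + pi / 2) / pi)
  if (tilt <= -pi / 2) tilt <- tilt + pi
  list(center = c(cx, cy), semi_major = semi_major,
       semi_minor = semi_minor, tilt = tilt)
}

# Build conic coefficients from geometric parameters (used by the scene
# generator's ground truth and by tests).
geometry_to_conic <- function(center, semi_major, semi_minor, tilt = 0) {
  stopifnot(semi_major > 0, semi_minor > 0)
  ct <- cos(tilt); st <- sin(tilt)
  a2 <- semi_major^2; b2 <- semi_minor^2
  A <- ct^2 / a2 + st^2 / b2
  B <- 2 * ct * st * (1 / a2 - 1 / b2)
  C <- st^2 / a2 + ct^2 / b2
  cx <- center[1]; cy <- center[2]
  D <- -2 * A * cx - B * cy
  E <- -B * cx - 2 * C * cy
  F <- A * cx^2 + B * cx * cy + C * cy^2 - 1
  c(A, B, C, D, E, F)
}

make_ellipse_fit <- function(coefs, method, n_points) {
  geom <- conic_to_geometry(coefs)
  if (is.null(geom)) return(empty_result("no_ellipse", "conic is not a real ellipse"))
  coefs <- coefs / sqrt(sum(coefs^2))
  if (coefs[1] + coefs[3] < 0) coefs <- -coefs
  names(coefs) <- c("A", "B", "C", "D", "E", "F")
  structure(list(conic = coefs, center = geom$center,
                 semi_major = geom$semi_major, semi_minor = geom$semi_minor,
                 tilt = geom$tilt, method = method, n_points = n_points),
            class = "ellipse_fit")
}

## ---- mirror completion ------------------------------------------------------

#' Complete a visible arc by point reflection
#'
#' The camera sees only one side of the elliptical liquid boundary. A copy of
#' the detected arc is rotated 180 degrees about the arc's centroid (a point
#' reflection), supplying the opposite side, and then translated vertically so
#' that its lowest point lies `bottom_offset` rows above the bottom image
#' edge. The vertical placement of the synthetic opposite side is a heuristic;
#' its default of 50 px was chosen for measurement stability and downstream
#' calibration absorbs the systematic bias it introduces.
#'
#' @param arc An `arc_segment` (see [extract_level_segment()]) or a two-column
#'   matrix/data frame of (col, row) points, 0-based.
#' @param bottom_offset Rows between the copy's lowest point and the bottom
#'   image edge (default 50).
#' @param image_shape Integer vector `c(rows, cols)`.
#' @return A two-column matrix of (x = col, y = row) points containing the
#'   original arc and its reflected copy (twice the input cardinality).
#' @export
mirror_segment <- function(arc, bottom_offset = 50, image_shape) {
  pts <- as.matrix(as.data.frame(arc)[, c("col", "row")])
  if (nrow(pts) == 0) stop("arc is empty")
  rows <- image_shape[1]
  if (bottom_offset < 0 || bottom_offset >= rows) {
    stop("bottom_offset must lie in [0, rows)")
  }
  ctr <- colMeans(pts)
  refl <- cbind(2 * ctr[1] - pts[, 1], 2 * ctr[2] - pts[, 2])
  target_bottom <- (rows - 1) - bottom_offset
  shift <- target_bottom - max(refl[, 2])
  refl[, 2] <- refl[, 2] + shift
  if (min(refl[, 2]) < 0) {
    stop("bottom_offset pushes the reflected copy above the image top")
  }
  out <- rbind(pts, refl)
  colnames(out) <- c("x", "y")
  rownames(out) <- NULL
  out
}

## ---- ellipse fitting --------------------------------------------------------

#' Fit an ellipse to scattered points
#'
#' Algebraic least-squares fit of the general conic
#' \eqn{A x^2 + B x y + C y^2 + D x + E y + F = 0} followed by extraction of
#' the geometric parameters (center, semi-axes, tilt) by removing the tilt
#' with a rotation. Three classic fitters are provided:
#' \describe{
#'   \item{`ls_conic`}{plain algebraic least squares with the coefficient
#'     vector constrained to unit norm; the fitted conic is classified
#'     afterwards and rejected when it is not an ellipse.}
#'   \item{`direct`}{the ellipse-specific direct fit with the constraint
#'     \eqn{4AC - B^2 = 1}, which always returns an ellipse when one exists.}
#'   \item{`taubin`}{Taubin's gradient-weighted normalization.}
#' }
#' Input coordinates are centered and scaled internally for numerical
#' conditioning; the returned conic is in the original coordinates.
#'
#' @param points Two-column matrix or data frame of (x, y) points.
#' @param method One of `"ls_conic"` (default), `"direct"`, `"taubin"`.
#' @return An object of class `"ellipse_fit"` with elements `conic` (named
#'   A..F, unit norm), `center`, `semi_major`, `semi_minor`, `tilt` (radians,
#'   angle of the major axis), `method`, `n_points`; or a typed
#'   [empty_result()] (`"no_ellipse"`) when the best-fitting conic is not a
#'   real ellipse or the input is degenerate.
#' @export
fit_ellipse <- function(points, method = c("ls_conic", "direct", "taubin")) {
  method <- match.arg(method)
  pts <- as.matrix(points)
  if (ncol(pts) != 2) stop("points must have two columns (x, y)")
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  n <- nrow(pts)
  if (n < 5) return(empty_result("no_ellipse", "fewer than 5 points"))
  # normalize for conditioning
  mx <- mean(pts[, 1]); my <- mean(pts[, 2])
  s <- mean(sqrt((pts[, 1] - mx)^2 + (pts[, 2] - my)^2))
  if (s < .Machine$double.eps) return(empty_result("no_ellipse", "coincident points"))
  u <- (pts[, 1] - mx) / s
  v <- (pts[, 2] - my) / s
  coefs_n <- switch(method,
    ls_conic = fit_conic_lsq(u, v),
    direct   = fit_conic_direct(u, v),
    taubin   = fit_conic_taubin(u, v))
  if (is.null(coefs_n)) return(empty_result("no_ellipse", "degenerate design"))
  # denormalize: conic matrix transforms as M_x = t(T) %*% M_uv %*% T
  Tm <- matrix(c(1 / s, 0, -mx / s, 0, 1 / s, -my / s, 0, 0, 1), 3, 3, byrow = TRUE)
  coefs <- matrix_to_conic(t(Tm) %*% conic_to_matrix(coefs_n) %*% Tm)
  make_ellipse_fit(coefs, method, n)
}

# plain algebraic LS: smallest right singular vector of the design matrix
fit_conic_lsq <- function(u, v) {
  D <- cbind(u^2, u * v, v^2, u, v, 1)
  sv <- svd(D, nu = 0, nv = 6)
  sv$v[, 6]
}

# direct ellipse-specific fit (Halir & Flusser formulation of the 4AC-B^2=1
# constrained problem)
fit_conic_direct <- function(u, v) {
  D1 <- cbind(u^2, u * v, v^2)
  D2 <- cbind(u, v, rep(1, length(u)))
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(Tm)) return(NULL)
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0) return(NULL)
  a1 <- evec[, ok[1]]
  c(a1, as.vector(Tm %*% a1))
}

# Taubin fit: minimize t(theta) M theta subject to t(theta) N theta = 1 where
# N is the gradient covariance of the conic polynomial. The constant-term row
# of N is identically zero, so F is eliminated through the stationarity
# condition and a 5x5 symmetric generalized eigenproblem remains.
fit_conic_taubin <- function(u, v) {
  n <- length(u)
  Z <- cbind(u^2, u * v, v^2, u, v, 1)
  M <- crossprod(Z) / n
  Zx <- cbind(2 * u, v, rep(0, n), rep(1, n), rep(0, n), rep(0, n))
  Zy <- cbind(rep(0, n), u, 2 * v, rep(0, n), rep(1, n), rep(0, n))
  N <- (crossprod(Zx) + crossprod(Zy)) / n
  if (M[6, 6] < .Machine$double.eps) return(NULL)
  Mr <- M[1:5, 1:5] - tcrossprod(M[1:5, 6]) / M[6, 6]
  Nr <- N[1:5, 1:5]
  U <- tryCatch(chol(Nr), error = function(e) NULL)
  if (is.null(U)) return(NULL)
  Ui <- backsolve(U, diag(5))
  W <- t(Ui) %*% Mr %*% Ui
  ev <- eigen((W + t(W)) / 2, symmetric = TRUE)
  theta5 <- Ui %*% ev$vectors[, 5]  # smallest eigenvalue
  f <- -sum(M[6, 1:5] * theta5) / M[6, 6]
  c(theta5, f)
}

#' @export
print.ellipse_fit <- function(x, digits = 4, ...) {
  cat("Ellipse fit (", x$method, ", ", x$n_points, " points)\n", sep = "")
  cat("  center     : (", round(x$center[1], digits), ", ",
      round(x$center[2], digits), ") px\n", sep = "")
  cat("  semi-axes  : ", round(x$semi_major, digits), " x ",
      round(x$semi_minor, digits), " px\n", sep = "")
  cat("  tilt       : ", round(x$tilt, digits), " rad\n", sep = "")
  invisible(x)
}

## ---- measurements -----------------------------------------------------------

#' Extract level and area measurements from a fitted ellipse
#'
#' The liquid level in pixels is the height of the horizontal line tangent to
#' the top of the ellipse, measured from the bottom image edge
#' (`level_px = rows - y_top`); with this convention a fuller glass, whose
#' boundary arc sits nearer the top of the image, yields a larger level.
#' The area is \eqn{\pi \cdot a \cdot b} with a, b the semi-axes, and is
#' therefore invariant under tilt. The vertical half-extent of a tilted
#' ellipse is \eqn{\sqrt{a^2 \sin^2\phi + b^2 \cos^2\phi}} where \eqn{\phi}
#' is the major-axis tilt.
#'
#' @param ellipse An `ellipse_fit` object (or any list with `center`,
#'   `semi_major`, `semi_minor`, `tilt`).
#' @param image_shape Integer vector `c(rows, cols)`.
#' @return Object of class `"vessel_measurement"`: list with `level_px`,
#'   `area_px2`, and `y_top` (row of the tangent line, 0-based).
#' @export
measure_ellipse <- function(ellipse, image_shape) {
  if (is_empty_result(ellipse)) return(ellipse)
  rows <- image_shape[1]
  a <- ellipse$semi_major; b <- ellipse$semi_minor; phi <- ellipse$tilt
  half_v <- sqrt(a^2 * sin(phi)^2 + b^2 * cos(phi)^2)
  y_top <- ellipse$center[2] - half_v
  structure(list(level_px = rows - y_top,
                 area_px2 = pi * a * b,
                 y_top = y_top),
            class = "vessel_measurement")
}

#' @export
print.vessel_measurement <- function(x, digits = 2, ...) {
  cat("level: ", round(x$level_px, digits), " px,  area: ",
      round(x$area_px2, digits), " px^2\n", sep = "")
  invisible(x)
}
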