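# Pixel-to-metric calibration: a quadratic map from level in pixels to level
# in mm, and a two-term exponential map from ellipse area in px^2 to glass
# sectional area in mm^2, each with dof-corrected fit statistics, plus an
# iterative residual-based outlier rule for calibration tables.

#' Read a calibration table
#'
#' Columns: `image`, `level_mm`, `diameter_mm`, `calc_vol_ml`, `level_px`,
#' `area_px2`, `derived_vol_ml`, `outlier`. The bundled table (the package's
#' regression fixture) records a calibration session on the default glass:
#' ground-truth level and diameter at six fill levels, three images each,
#' with the rows excluded from the original analysis flagged as outliers
#' (including one image from which no measurement could be derived).
#'
#' @param path CSV path; default the bundled table.
#' @return Data frame of class `"calibration_table"`.
#' @export
read_calibration_table <- function(path = system.file("extdata", "table2.csv",
                                                      package = "vesselcam")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image", "level_mm", "diameter_mm", "calc_vol_ml",
            "level_px", "area_px2", "derived_vol_ml", "outlier")
  if (!all(need %in% names(tab))) {
    stop("calibration table must have columns: ", paste(need, collapse = ", "))
  }
  tab$outlier <- as.logical(tab$outlier)
  stopifnot(all(tab$level_mm > 0), all(tab$diameter_mm > 0))
  class(tab) <- c("calibration_table", "data.frame")
  tab
}

# dof-corrected fit statistics shared by both models
fit_stats <- function(residuals, y, n_par) {
  n <- length(residuals)
  dof <- n - n_par
  ss_res <- sum(residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  list(r_squared = 1 - ss_res / ss_tot,
       std_error = sqrt(ss_res / dof),
       n = n, dof = dof)
}

#' Fit the quadratic level calibration model
#'
#' Ordinary least squares of `level_mm = p1*px^2 + p2*px + p3` on paired
#' (level in px, level in mm) observations. The reported `std_error` is the
#' degree-of-freedom corrected RMSE `sqrt(SS_res / (n - 3))`.
#'
#' @param level_px Derived levels in pixels.
#' @param level_mm Ground-truth levels in mm.
#' @return Object of class `"poly2_fit"`: coefficients `p1` (mm/px^2), `p2`
#'   (mm/px), `p3` (mm), `stats` (list `r_squared`, `std_error`, `n`, `dof`),
#'   and the underlying `lm` fit. Supports `coef`, `predict`, `summary`,
#'   `print`.
#' @export
fit_level_model <- function(level_px, level_mm) {
  stopifnot(length(level_px) == length(level_mm))
  ok <- is.finite(level_px) & is.finite(level_mm)
  x <- level_px[ok]; y <- level_mm[ok]
  if (length(x) < 4) stop("need at least 4 complete (level_px, level_mm) pairs")
  if (length(unique(x)) < 3) stop("rank-deficient design: too few distinct level_px values")
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- stats::coef(fit)
  structure(list(p1 = unname(cf[3]), p2 = unname(cf[2]), p3 = unname(cf[1]),
                 stats = fit_stats(stats::resid(fit), y, 3), lm = fit),
            class = "poly2_fit")
}

#' Construct calibration models from known coefficients
#'
#' Builds `"poly2_fit"` / `"exp2_fit"` objects directly from coefficients
#' (e.g. published values), usable with [predict_level()] /
#' [predict_area()]; fit statistics are absent.
#'
#' @param p1,p2,p3 Quadratic coefficients (mm/px^2, mm/px, mm).
#' @return A `"poly2_fit"` (without `stats`/`lm`).
#' @export
poly2_model <- function(p1, p2, p3) {
  stopifnot(is.finite(p1), is.finite(p2), is.finite(p3))
  structure(list(p1 = p1, p2 = p2, p3 = p3, stats = NULL, lm = NULL),
            class = "poly2_fit")
}

#' @rdname poly2_model
#' @param a,b,c,d Two-term exponential coefficients (mm^2, 1/px^2, mm^2,
#'   1/px^2).
#' @return An `"exp2_fit"` (without `stats`/`nls`).
#' @export
exp2_model <- function(a, b, c, d) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c), is.finite(d))
  structure(list(a = a, b = b, c = c, d = d, stats = NULL, nls = NULL),
            class = "exp2_fit")
}

#' @export
coef.poly2_fit <- function(object, ...) {
  c(p1 = object$p1, p2 = object$p2, p3 = object$p3)
}

#' Predict level in mm from level in pixels
#'
#' @param model A `"poly2_fit"`.
#' @param level_px Levels in pixels.
#' @return Levels in mm.
#' @export
predict_level <- function(model, level_px) {
  stopifnot(inherits(model, "poly2_fit"))
  if (any(!is.finite(level_px))) stop("level_px must be finite")
  model$p1 * level_px^2 + model$p2 * level_px + model$p3
}

#' @export
predict.poly2_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(stats::fitted(object$lm))
  predict_level(object, newdata)
}

#' @export
print.poly2_fit <- function(x, ...) {
  cat("Quadratic level calibration: mm =",
      signif(x$p1, 3), "* px^2 +", signif(x$p2, 3), "* px +",
      signif(x$p3, 3), "\n")
  if (!is.null(x$stats)) {
    cat(sprintf("  R^2 = %.4f, std. error = %.4f mm (n = %d, dof = %d)\n",
                x$stats$r_squared, x$stats$std_error, x$stats$n, x$stats$dof))
  }
  invisible(x)
}

#' @export
summary.poly2_fit <- function(object, ...) {
  print(object)
  invisible(c(coef(object), unlist(object$stats)))
}

#' Fit the two-term exponential area calibration model
#'
#' Nonlinear least squares of
#' `area_mm2 = a*exp(b*x) + c*exp(d*x)` (x = area in px^2), fit with
#' Levenberg-Marquardt from a deterministic multistart: slow-decay rates
#' `d0` estimated from a log-linear fit to the detrended response tail
#' (plus fixed fallbacks), fast rates `b0` over `{+-1e-6, +-1e-5}`, and for
#' each rate pair the amplitudes solved linearly. The best converged start
#' (smallest residual sum of squares) is kept.
#'
#' @param area_px2 Derived ellipse areas in px^2.
#' @param area_mm2 Ground-truth sectional areas in mm^2 (e.g.
#'   `pi * (diameter_mm / 2)^2`).
#' @return Object of class `"exp2_fit"`: coefficients `a`, `b`, `c`, `d`,
#'   `stats` (as in [fit_level_model()], with `n - 4` dof), and the
#'   underlying `nls` object. Supports `coef`, `predict`, `summary`, `print`.
#' @export
fit_area_model <- function(area_px2, area_mm2) {
  stopifnot(length(area_px2) == length(area_mm2))
  ok <- is.finite(area_px2) & is.finite(area_mm2)
  x <- area_px2[ok]; y <- area_mm2[ok]
  if (length(x) < 5) stop("need at least 5 complete (area_px2, area_mm2) pairs")

  # deterministic start list
  d0_set <- c(-1e-3, -1e-4, -1e-5)
  dt <- y - mean(y)
  pos <- dt > 0 & x > stats::median(x)
  if (sum(pos) >= 3) {
    sl <- stats::coef(stats::lm(log(dt[pos]) ~ x[pos]))[2]
    if (is.finite(sl) && sl != 0) d0_set <- c(-abs(sl), d0_set)
  }
  b0_set <- c(1e-6, -1e-6, 1e-5, -1e-5)

  best <- NULL
  dat <- data.frame(x = x, y = y)
  for (b0 in b0_set) for (d0 in d0_set) {
    if (abs(b0 - d0) < 1e-12) next
    X <- cbind(exp(b0 * x), exp(d0 * x))
    ac <- tryCatch(qr.solve(X, y), error = function(e) NULL)
    if (is.null(ac) || any(!is.finite(ac))) next
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(b * x) + cc * exp(d * x), data = dat,
                        start = list(a = ac[1], b = b0, cc = ac[2], d = d0),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(stats::resid(fit)^2)
    if (is.null(best) || ss < best$ss) best <- list(ss = ss, fit = fit)
  }
  if (is.null(best)) {
    stop("two-term exponential fit failed to converge from any start; ",
         "inspect the (area_px2, area_mm2) pairs for degeneracy")
  }
  cf <- stats::coef(best$fit)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 c = unname(cf["cc"]), d = unname(cf["d"]),
                 stats = fit_stats(stats::resid(best$fit), y, 4),
                 nls = best$fit),
            class = "exp2_fit")
}

#' @export
coef.exp2_fit <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c, d = object$d)
}

#' Predict sectional area in mm^2 from ellipse area in px^2
#'
#' Evaluates the two-term exponential model; errors when the prediction is
#' non-positive (outside the calibrated range the model has no physical
#' meaning).
#'
#' @param model An `"exp2_fit"`.
#' @param area_px2 Areas in px^2.
#' @return Areas in mm^2.
#' @export
predict_area <- function(model, area_px2) {
  stopifnot(inherits(model, "exp2_fit"))
  if (any(!is.finite(area_px2))) stop("area_px2 must be finite")
  out <- model$a * exp(model$b * area_px2) + model$c * exp(model$d * area_px2)
  if (any(out <= 0)) {
    stop("area model predicts a non-positive section; input outside the calibrated range")
  }
  out
}

#' @export
predict.exp2_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(stats::fitted(object$nls))
  predict_area(object, newdata)
}

#' @export
print.exp2_fit <- function(x, ...) {
  cat("Two-term exponential area calibration: mm^2 =",
      signif(x$a, 3), "* exp(", signif(x$b, 3), "* x ) +",
      signif(x$c, 3), "* exp(", signif(x$d, 3), "* x )\n")
  if (!is.null(x$stats)) {
    cat(sprintf("  R^2 = %.4f, std. error = %.4f mm^2 (n = %d, dof = %d)\n",
                x$stats$r_squared, x$stats$std_error, x$stats$n, x$stats$dof))
  }
  invisible(x)
}

#' @export
summary.exp2_fit <- function(object, ...) {
  print(object)
  invisible(c(coef(object), unlist(object$stats)))
}

#' Flag calibration-table outliers by iterated standardized residuals
#'
#' Fits both calibration models on the currently unflagged complete rows,
#' flags every row whose standardized residual exceeds `k` in either fit,
#' and repeats until the flag set is stable. Residuals are standardized by
#' the robust scale `mad(residuals)` rather than the RMSE: gross outliers
#' that occur in pairs (as failed low-level images tend to) inflate the RMSE
#' enough to mask each other, while the MAD is insensitive to them. Rows
#' without derived measurements are flagged as failed from the start.
#' Errors if more than half of the usable rows end up flagged, since the
#' calibration would then be meaningless.
#'
#' @param table A `"calibration_table"` (or data frame with its columns).
#' @param k Residual multiplier (default 2.5).
#' @param max_iter Safety cap on iterations.
#' @return Logical vector, one flag per table row.
#' @export
flag_outliers <- function(table, k = 2.5, max_iter = 10) {
  complete <- is.finite(table$level_px) & is.finite(table$area_px2)
  if (sum(complete) < 6) stop("need at least 6 complete rows to flag outliers")
  flags <- !complete
  area_mm2 <- pi * (table$diameter_mm / 2)^2
  # Hampel-style leverage guard: a derived pixel value far outside the bulk
  # of its own column is a corrupt measurement regardless of how well the
  # (high-leverage) fit bends to accommodate it
  hampel <- function(x) {
    s <- stats::mad(x[complete])
    complete & s > 0 & abs(x - stats::median(x[complete])) / s > k
  }
  flags <- flags | hampel(table$level_px) | hampel(table$area_px2)
  for (it in seq_len(max_iter)) {
    use <- !flags
    lm_fit <- fit_level_model(table$level_px[use], table$level_mm[use])
    ar_fit <- fit_area_model(table$area_px2[use], area_mm2[use])
    rl <- ra <- rep(Inf, nrow(table))
    rl[complete] <- table$level_mm[complete] -
      predict_level(lm_fit, table$level_px[complete])
    pa <- ar_fit$a * exp(ar_fit$b * table$area_px2[complete]) +
      ar_fit$c * exp(ar_fit$d * table$area_px2[complete])
    ra[complete] <- area_mm2[complete] - pa
    # floor the robust scale so exactly-fitting tables (residuals ~ machine
    # epsilon) do not standardize their own noise into flags
    sl <- max(stats::mad(rl[use & complete]),
              1e-8 * diff(range(table$level_mm[use & complete])))
    sa <- max(stats::mad(ra[use & complete]),
              1e-8 * diff(range(area_mm2[use & complete])))
    new_flags <- !complete | abs(rl) / sl > k | abs(ra) / sa > k
    if (identical(new_flags, flags)) break
    flags <- new_flags
  }
  if (sum(flags & complete) > 0.5 * sum(complete)) {
    stop("more than half of the complete rows flagged: calibration unusable")
  }
  flags
}
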