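# Agreement statistics between inferred and reference volumes:
# Bland-Altman mean difference, limits of agreement, and the coefficient of
# variation of the differences relative to the grand mean.

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `estimate - reference`. Reported are the mean
#' difference (bias), the sample standard deviation of the differences, the
#' limits of agreement `mean +/- 1.96 * SD`, the standard error of the mean
#' difference `SD / sqrt(n)`, and the coefficient of variation
#' `100 * SD / mean(pairwise means)` in percent. Both the SD of the
#' differences and its standard error are exposed, since "standard error"
#' is used loosely for either in parts of the applied literature.
#'
#' @param reference Reference values (mL).
#' @param estimate Estimated values (mL), same length, n >= 2.
#' @return Object of class `"bland_altman"`: `n`, `mean_difference`,
#'   `sd_differences`, `limits_of_agreement` (length-2), `se_of_mean_difference`,
#'   `cv_percent`, plus the `pairs` (means and differences) for plotting.
#' @export
bland_altman <- function(reference, estimate) {
  if (length(reference) != length(estimate)) {
    stop("reference and estimate must have the same length")
  }
  ok <- is.finite(reference) & is.finite(estimate)
  reference <- reference[ok]; estimate <- estimate[ok]
  n <- length(reference)
  if (n < 2) stop("need at least 2 complete pairs")
  d <- estimate - reference
  m <- (estimate + reference) / 2
  md <- mean(d)
  sdd <- stats::sd(d)
  structure(list(n = n,
                 mean_difference = md,
                 sd_differences = sdd,
                 limits_of_agreement = c(md - 1.96 * sdd, md + 1.96 * sdd),
                 se_of_mean_difference = sdd / sqrt(n),
                 cv_percent = 100 * sdd / mean(m),
                 pairs = data.frame(mean = m, difference = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 2, ...) {
  cat("Bland-Altman agreement (n = ", x$n, ")\n", sep = "")
  cat("  mean difference     : ", round(x$mean_difference, digits), " mL\n", sep = "")
  cat("  SD of differences   : ", round(x$sd_differences, digits), " mL\n", sep = "")
  cat("  limits of agreement : [", round(x$limits_of_agreement[1], digits),
      ", ", round(x$limits_of_agreement[2], digits), "] mL\n", sep = "")
  cat("  SE of mean difference: ", round(x$se_of_mean_difference, digits),
      " mL\n", sep = "")
  cat("  CV                  : ", round(x$cv_percent, 1), " %\n", sep = "")
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$pairs$mean, x$pairs$difference,
                 xlab = "Mean of reference and estimate (mL)",
                 ylab = "Difference, estimate - reference (mL)",
                 main = "Bland-Altman agreement", pch = 19, ...)
  graphics::abline(h = x$mean_difference, lty = 1)
  graphics::abline(h = x$limits_of_agreement, lty = 2)
  invisible(x)
}

#' Write a Bland-Altman plot to a PNG file
#'
#' @param report A `"bland_altman"` object.
#' @param path Output PNG path.
#' @param width,height Device size in px.
#' @return Invisibly, the path.
#' @export
plot_bland_altman <- function(report, path, width = 640, height = 480) {
  stopifnot(inherits(report, "bland_altman"))
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  plot(report)
  invisible(path)
}
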