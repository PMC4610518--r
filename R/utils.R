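# Internal helpers shared across the pipeline.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

clamp01 <- function(x) {
  x[] <- pmin(1, pmax(0, x))
  x
}

#' Typed empty outcome for pipeline stages
#'
#' Stages that can legitimately find nothing (an empty glass has no liquid
#' level; degenerate points admit no ellipse) return this typed value rather
#' than raising an error, so batch runs can record the row as missing and
#' continue.
#'
#' @param reason Character, short machine-readable reason (e.g. `"no_level"`,
#'   `"no_ellipse"`).
#' @param detail Optional human-readable detail.
#' @return An object of class `"vessel_empty"`.
#' @export
empty_result <- function(reason, detail = "") {
  structure(list(reason = reason, detail = detail), class = "vessel_empty")
}

#' @rdname empty_result
#' @param x Object to test.
#' @export
is_empty_result <- function(x) inherits(x, "vessel_empty")

#' @export
print.vessel_empty <- function(x, ...) {
  cat("<empty result:", x$reason,
      if (nzchar(x$detail)) paste0("- ", x$detail) else "", ">\n")
  invisible(x)
}

# validate a grayscale image matrix
check_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix (rows x cols)", call. = FALSE)
  }
  if (anyNA(image) || min(image) < -1e-9 || max(image) > 1 + 1e-9) {
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  }
  invisible(image)
}

check_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  if (is.logical(mask)) return(invisible(mask))
  if (!all(mask %in% c(0, 1))) stop("mask must be binary", call. = FALSE)
  invisible(mask)
}

as_binary <- function(mask) {
  if (is.logical(mask)) mask else mask > 0.5
}
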