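#' Geometric description of a conical drinking glass
#'
#' The glass is modelled by its interior wall radius as a function of the
#' liquid level. The bundled calibration glass narrows toward the rim: the
#' measured diameter shrinks from 73 mm at a 10 mm level to 64 mm at 60 mm,
#' which a linear taper captures well.
#'
#' @param height_mm Interior height of the glass in mm.
#' @param radius_at Function mapping a level in mm (0 = base) to the wall
#'   radius in mm; must be positive over `[0, height_mm]`.
#' @param reference_level_mm The "top level" used as the fixed reference for
#'   volume computation (the highest level recorded during calibration).
#' @return Object of class `"glass_spec"`.
#' @export
glass_spec <- function(height_mm, radius_at, reference_level_mm = height_mm) {
  stopifnot(is.numeric(height_mm), height_mm > 0, is.function(radius_at),
            reference_level_mm >= 0, reference_level_mm <= height_mm)
  probe <- radius_at(seq(0, height_mm, length.out = 64))
  if (any(!is.finite(probe)) || any(probe <= 0)) {
    stop("radius_at must be positive and finite over [0, height_mm]")
  }
  structure(list(height_mm = height_mm, radius_at = radius_at,
                 reference_level_mm = reference_level_mm),
            class = "glass_spec")
}

#' Default calibration glass
#'
#' Linear-taper glass matching the bundled calibration table: radius
#' `37.4 - 0.09 * level` mm (diameter 73.4 mm at the base, narrowing upward),
#' interior height 70 mm, reference level 60 mm.
#'
#' @return A [glass_spec()].
#' @export
default_glass <- function() {
  glass_spec(height_mm = 70,
             radius_at = function(level_mm) 37.4 - 0.09 * level_mm,
             reference_level_mm = 60)
}

#' @export
print.glass_spec <- function(x, ...) {
  cat("Conical glass: height ", x$height_mm, " mm, radius ",
      round(x$radius_at(0), 1), " mm (base) -> ",
      round(x$radius_at(x$height_mm), 1), " mm (rim), reference level ",
      x$reference_level_mm, " mm\n", sep = "")
  invisible(x)
}
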