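# Volume estimation: conical frustum geometry applied to calibrated levels
# and radii, for both the ground-truth pathway (measured mm) and the inferred
# pathway (pixels through the calibration models).

#' Conical frustum volume
#'
#' \deqn{V = \frac{\pi}{3} h (r_1^2 + r_2^2 + r_1 r_2)}
#' with `h` in mm and radii in mm; returned in mL (1 mL = 1000 mm^3).
#' With `r1 = r2 = r` this reduces to the cylinder `pi r^2 h`; with one
#' radius 0 it is a cone.
#'
#' @param h Height between the two levels, mm (>= 0).
#' @param r1,r2 Radii at the two levels, mm (>= 0).
#' @return Volume in mL.
#' @export
frustum_volume <- function(h, r1, r2) {
  if (any(c(h, r1, r2) < 0)) stop("frustum arguments must be non-negative")
  (pi / 3) * h * (r1^2 + r2^2 + r1 * r2) / 1000
}

#' Radius of a circle with the given area
#'
#' @param area Area in mm^2 (> 0).
#' @return Radius in mm, `sqrt(area / pi)`.
#' @export
radius_from_area <- function(area) {
  if (any(area <= 0)) stop("area must be positive")
  sqrt(area / pi)
}

# reference (top level, radius) used by the volume convention; default from a
# calibration table's maximal-level rows
reference_from_table <- function(table) {
  i <- which.max(table$level_mm)
  list(level_mm = table$level_mm[i], radius_mm = table$diameter_mm[i] / 2)
}

#' Ground-truth volume of a calibration row
#'
#' The calibration table's volume column follows the convention
#' `frustum_volume(h = level_mm, r1 = reference radius, r2 = diameter/2)`,
#' i.e. the row's own level as the height and the radius at the maximal
#' recorded level as the fixed first radius — the convention that reproduces
#' the recorded volumes. The literal reading "height between the reference
#' level and this level" (`h = reference_level - level`) is also available
#' via `convention = "gap"`, but does not reproduce the recorded column.
#'
#' @param level_mm Row's liquid level, mm.
#' @param diameter_mm Row's glass diameter at the level, mm.
#' @param reference List with `level_mm` and `radius_mm` of the reference
#'   (maximal-level) row; see [reference_from_table()] behaviour in
#'   [run_end_to_end()].
#' @param convention `"table"` (default) or `"gap"`.
#' @return Object of class `"volume_estimate"`: list with `volume_ml`,
#'   `h_mm`, `r1_mm`, `r2_mm`, `provenance`.
#' @export
ground_truth_volume <- function(level_mm, diameter_mm,
                                reference = list(level_mm = 60, radius_mm = 32),
                                convention = c("table", "gap")) {
  convention <- match.arg(convention)
  if (!is.finite(level_mm) || !is.finite(diameter_mm)) {
    stop("level_mm and diameter_mm must be finite")
  }
  h <- if (convention == "table") level_mm else reference$level_mm - level_mm
  v <- frustum_volume(h, reference$radius_mm, diameter_mm / 2)
  structure(list(volume_ml = v, h_mm = h, r1_mm = reference$radius_mm,
                 r2_mm = diameter_mm / 2, provenance = "ground_truth"),
            class = "volume_estimate")
}

#' Inferred volume from a pixel measurement
#'
#' Converts the pixel measurement to metric units through the calibration
#' models — level via the quadratic map, radius via the square root of the
#' exponential area map — and applies the same frustum convention as
#' [ground_truth_volume()].
#'
#' @param m A `"vessel_measurement"` (or list with `level_px`, `area_px2`).
#' @param level_model A `"poly2_fit"`.
#' @param area_model An `"exp2_fit"`.
#' @param reference As in [ground_truth_volume()].
#' @return A `"volume_estimate"` with provenance `"inferred"`.
#' @export
inferred_volume <- function(m, level_model, area_model,
                            reference = list(level_mm = 60, radius_mm = 32)) {
  if (is_empty_result(m)) return(m)
  level_mm <- predict_level(level_model, m$level_px)
  r_mm <- radius_from_area(predict_area(area_model, m$area_px2))
  v <- frustum_volume(level_mm, reference$radius_mm, r_mm)
  structure(list(volume_ml = v, h_mm = level_mm,
                 r1_mm = reference$radius_mm, r2_mm = r_mm,
                 provenance = "inferred"),
            class = "volume_estimate")
}

#' Consumed volume between two measurements
#'
#' The volume of the frustum between the two calibrated levels, with the
#' calibrated radii at those levels: the amount drunk between the two frames.
#' Symmetric in its arguments (the height is `|l1 - l2|`).
#'
#' @param m1,m2 `"vessel_measurement"` objects.
#' @param level_model,area_model Calibration models.
#' @return Volume difference in mL.
#' @export
volume_difference <- function(m1, m2, level_model, area_model) {
  l1 <- predict_level(level_model, m1$level_px)
  l2 <- predict_level(level_model, m2$level_px)
  r1 <- radius_from_area(predict_area(area_model, m1$area_px2))
  r2 <- radius_from_area(predict_area(area_model, m2$area_px2))
  frustum_volume(abs(l1 - l2), r1, r2)
}

#' @export
print.volume_estimate <- function(x, digits = 1, ...) {
  cat(x$provenance, " volume: ", round(x$volume_ml, digits), " mL (h = ",
      round(x$h_mm, 1), " mm, r1 = ", round(x$r1_mm, 1), " mm, r2 = ",
      round(x$r2_mm, 1), " mm)\n", sep = "")
  invisible(x)
}
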