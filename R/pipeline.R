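# Pipeline wiring: configuration, single-image measurement, batch
# measurement, and the end-to-end simulate -> measure -> calibrate ->
# volume -> agreement run.

#' Pipeline configuration
#'
#' Bundles and validates all stage parameters. Defaults are the package's
#' documented settings for 160x120 frames.
#'
#' @param disk_radius Pre-blur disk radius, px.
#' @param edge Edge filter: `"sobel"` or `"vesselness"`.
#' @param sobel_threshold Sobel gradient threshold (number or `"auto"`).
#' @param vesselness_scales Scales for the vesselness filter, px.
#' @param line_length Structuring-element length for mask refinement, px.
#' @param scan A [scan_params()].
#' @param prune_width,smooth_window Arc extraction parameters, px. The
#'   pipeline default for `prune_width` is 12: a 2-px level line, after the
#'   disk pre-blur and dilation, yields a refined band 8-12 px tall, which
#'   pruning must keep while still dropping larger attached clutter.
#' @param mirror_offset Bottom offset of the reflected arc copy, px.
#' @param fitter Ellipse fitter: `"ls_conic"`, `"direct"` or `"taubin"`.
#' @param outlier_k Residual multiplier for [flag_outliers()].
#' @param seed Integer seed for every stochastic stage.
#' @return Validated list of class `"vessel_config"`.
#' @export
vessel_config <- function(disk_radius = 3, edge = c("sobel", "vesselness"),
                          sobel_threshold = 0.005,
                          vesselness_scales = c(1, 2, 3), line_length = 3,
                          scan = scan_params(), prune_width = 12,
                          smooth_window = 5, mirror_offset = 50,
                          fitter = c("ls_conic", "direct", "taubin"),
                          outlier_k = 2.5, seed = 1) {
  edge <- match.arg(edge)
  fitter <- match.arg(fitter)
  stopifnot(disk_radius >= 1, line_length >= 1, inherits(scan, "scan_params"),
            prune_width >= 1, smooth_window >= 1, mirror_offset >= 0,
            outlier_k > 0)
  structure(list(disk_radius = disk_radius, edge = edge,
                 sobel_threshold = sobel_threshold,
                 vesselness_scales = vesselness_scales,
                 line_length = line_length, scan = scan,
                 prune_width = prune_width, smooth_window = smooth_window,
                 mirror_offset = mirror_offset, fitter = fitter,
                 outlier_k = outlier_k, seed = as.integer(seed)),
            class = "vessel_config")
}

#' Measure liquid level and surface area in one image
#'
#' Runs the full measurement chain: disk pre-blur, edge mask (Sobel or
#' vesselness), morphological refinement, quadratic curve scan, arc
#' extraction, mirror completion, ellipse fit, and measurement. Returns a
#' `"vessel_measurement"` (`level_px`, `area_px2`) or a typed
#' [empty_result()] describing the first stage that found nothing (an empty
#' glass gives `"no_level"`; degenerate geometry gives `"no_ellipse"`).
#'
#' @param image Numeric matrix in \[0, 1\], or a file path.
#' @param config A [vessel_config()].
#' @return A `"vessel_measurement"` or an [empty_result()].
#' @export
measure_image <- function(image, config = vessel_config()) {
  if (is.character(image)) image <- read_gray(image)
  check_image(image)
  shape <- dim(image)
  blurred <- preblur(image, config$disk_radius)
  mask <- if (config$edge == "sobel") {
    sobel_mask(blurred, config$sobel_threshold)
  } else {
    v <- vesselness(blurred, config$vesselness_scales)
    v > vesselness_threshold(v)
  }
  mask <- refine_mask(mask, config$line_length)
  scan <- scan_curves(mask, config$scan)
  if (is_empty_result(scan)) return(scan)
  arc <- extract_level_segment(mask, scan, config$prune_width,
                               config$smooth_window)
  if (is_empty_result(arc)) return(arc)
  pts <- mirror_segment(arc, config$mirror_offset, shape)
  ell <- fit_ellipse(pts, config$fitter)
  if (is_empty_result(ell)) return(ell)
  measure_ellipse(ell, shape)
}

#' Measure a batch of images
#'
#' One row per input. Failures (unreadable file, no level, no ellipse) are
#' recorded with NA measurements and a status string rather than aborting
#' the batch.
#'
#' @param images Character vector of file paths, or a list of image matrices.
#' @param config A [vessel_config()].
#' @return Data frame with columns `image`, `level_px`, `area_px2`, `status`.
#' @export
run_measure <- function(images, config = vessel_config()) {
  nm <- if (is.character(images)) images else
    sprintf("image_%02d", seq_along(images))
  rows <- lapply(seq_along(nm), function(i) {
    m <- tryCatch(measure_image(if (is.character(images)) images[i] else
                                images[[i]], config),
                  error = function(e) empty_result("error", conditionMessage(e)))
    if (is_empty_result(m)) {
      data.frame(image = nm[i], level_px = NA_real_, area_px2 = NA_real_,
                 status = m$reason)
    } else {
      data.frame(image = nm[i], level_px = m$level_px, area_px2 = m$area_px2,
                 status = "ok")
    }
  })
  do.call(rbind, rows)
}

#' End-to-end synthetic run: simulate, measure, calibrate, evaluate
#'
#' Renders a sweep of fill levels of a glass, measures each frame with the
#' full pipeline, fits both calibration models on (measured px, ground-truth
#' mm) pairs, converts the measurements to volumes, and summarizes agreement
#' between inferred and ground-truth volumes. Optionally writes all
#' artifacts (frames, measurement CSV, model JSON, agreement JSON and plot)
#' to a directory.
#'
#' @param glass A [glass_spec()].
#' @param levels_mm Fill levels to render, mm.
#' @param reps Renders per level (distinct seeds).
#' @param sp_density Salt-and-pepper degradation applied to each frame.
#' @param config A [vessel_config()]; its seed controls rendering and noise.
#' @param out_dir Optional output directory for artifacts.
#' @return List with `measurements` (data frame incl. ground truth),
#'   `level_model`, `area_model`, `volumes` (data frame of reference and
#'   inferred volumes), and `agreement` (a `"bland_altman"`).
#' @export
run_end_to_end <- function(glass = default_glass(),
                           levels_mm = seq(10, 60, by = 10), reps = 3,
                           sp_density = 0, config = vessel_config(),
                           out_dir = NULL) {
  grid <- expand.grid(rep = seq_len(reps), level_mm = levels_mm)
  meas <- lapply(seq_len(nrow(grid)), function(i) {
    lev <- grid$level_mm[i]
    seed_i <- config$seed + 1000L * i
    sc <- render_scene(glass, fill_level_mm = lev, seed = seed_i)
    img <- if (sp_density > 0) {
      add_noise(sc$image, sp_density = sp_density, seed = seed_i + 1L)
    } else sc$image
    if (!is.null(out_dir)) {
      write_scene(list(image = img, truth = sc$truth), out_dir,
                  sprintf("scene_l%02d_r%d", lev, grid$rep[i]))
    }
    m <- tryCatch(measure_image(img, config),
                  error = function(e) empty_result("error", conditionMessage(e)))
    data.frame(level_mm = lev, rep = grid$rep[i],
               diameter_mm = 2 * glass$radius_at(lev),
               level_px = if (is_empty_result(m)) NA_real_ else m$level_px,
               area_px2 = if (is_empty_result(m)) NA_real_ else m$area_px2,
               status = if (is_empty_result(m)) m$reason else "ok")
  })
  meas <- do.call(rbind, meas)
  ok <- meas$status == "ok"
  if (sum(ok) < 5) stop("too few successful measurements to calibrate")

  level_model <- fit_level_model(meas$level_px[ok], meas$level_mm[ok])
  area_model <- fit_area_model(meas$area_px2[ok],
                               pi * (meas$diameter_mm[ok] / 2)^2)

  ref_level <- glass$reference_level_mm
  reference <- list(level_mm = ref_level,
                    radius_mm = glass$radius_at(ref_level))
  vols <- do.call(rbind, lapply(which(ok), function(i) {
    gt <- ground_truth_volume(meas$level_mm[i], meas$diameter_mm[i], reference)
    inf <- inferred_volume(list(level_px = meas$level_px[i],
                                area_px2 = meas$area_px2[i]),
                           level_model, area_model, reference)
    data.frame(level_mm = meas$level_mm[i], rep = meas$rep[i],
               reference_ml = gt$volume_ml, inferred_ml = inf$volume_ml)
  }))
  agreement <- bland_altman(vols$reference_ml, vols$inferred_ml)

  if (!is.null(out_dir)) {
    utils::write.csv(meas, file.path(out_dir, "measurements.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(level_model = coef(level_model), level_stats = level_model$stats,
           area_model = coef(area_model), area_stats = area_model$stats),
      file.path(out_dir, "models.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      agreement[c("n", "mean_difference", "sd_differences",
                  "limits_of_agreement", "se_of_mean_difference",
                  "cv_percent")],
      file.path(out_dir, "agreement.json"), auto_unbox = TRUE, digits = NA)
    plot_bland_altman(agreement, file.path(out_dir, "bland_altman.png"))
  }

  list(measurements = meas, level_model = level_model,
       area_model = area_model, volumes = vols, agreement = agreement)
}
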