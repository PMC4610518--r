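# Shared fixtures built in code. Scenes are rendered once per session and
# memoized, since several test files reuse the same frames.

.fixture_env <- new.env(parent = emptyenv())

fixture_scene <- function(fill = 40, seed = 5) {
  key <- sprintf("scene_%s_%s", fill, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- render_scene(fill_level_mm = fill, seed = seed)
  }
  .fixture_env[[key]]
}

# rasterize row = a col^2 + b col + c (0-based) into a logical mask
curve_mask <- function(rows, cols, a, b, c_) {
  m <- matrix(FALSE, rows, cols)
  col0 <- 0:(cols - 1)
  r <- round(a * col0^2 + b * col0 + c_)
  ok <- r >= 0 & r <= rows - 1
  m[cbind(r[ok] + 1, col0[ok] + 1)] <- TRUE
  m
}

# sample n points on an ellipse boundary (geometric parameters, image coords)
ellipse_points <- function(center, a, b, tilt = 0, n = 16,
                           theta = seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]) {
  x0 <- a * cos(theta); y0 <- b * sin(theta)
  cbind(x = center[1] + x0 * cos(tilt) - y0 * sin(tilt),
        y = center[2] + x0 * sin(tilt) + y0 * cos(tilt))
}

# the 14 non-outlier calibration pairs used throughout
table2_pairs <- function() {
  tab <- read_calibration_table()
  tab[!tab$outlier & is.finite(tab$level_px), ]
}

# independent recall scorer (1-px tolerance), kept separate from the
# package's internal implementation
arc_recall_for_test <- function(mask, arc_points) {
  hits <- vapply(seq_len(nrow(arc_points)), function(i) {
    r <- arc_points[i, "row"] + 1; c_ <- arc_points[i, "col"] + 1
    rr <- max(1, r - 1):min(nrow(mask), r + 1)
    cc <- max(1, c_ - 1):min(ncol(mask), c_ + 1)
    any(mask[rr, cc])
  }, logical(1))
  mean(hits)
}

# independent brute-force oracle: best (component, b, c) by exhaustive
# overlap counting, same tie-break order (smallest c, then smallest b)
brute_force_scan <- function(mask, params) {
  labels <- label_components(mask)
  rows <- nrow(mask); cols <- ncol(mask)
  bs <- seq(params$b_min, params$b_max, length.out = params$b_steps)
  best <- list(component = NA, overlap = 0, b = NA, c = NA)
  for (c_ in 0:(rows - 1)) for (b in bs) {
    counts <- integer(max(labels))
    for (col0 in 0:(cols - 1)) {
      r <- round(params$a * col0^2 + b * col0 + c_)
      if (r < 0 || r > rows - 1) next
      lab <- labels[r + 1, col0 + 1]
      if (lab > 0) counts[lab] <- counts[lab] + 1
    }
    if (length(counts) && max(counts) > best$overlap) {
      best <- list(component = which.max(counts), overlap = max(counts),
                   b = b, c = c_)
    }
  }
  best
}

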