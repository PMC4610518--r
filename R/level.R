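# Level detection: find the connected component of the gradient mask that is
# the liquid-level arc by scanning a family of downward-opening quadratic
# curves over the mask, then prune, bridge and smooth it into a per-column
# row trace.

#' Curve-scan parameters
#'
#' The liquid-level arc has an approximately quadratic image profile
#' `row = a*col^2 + b*col + c` (0-based pixel coordinates, col the
#' independent variable). The scan rasterizes this curve for every row
#' intercept `c` in the image and `b_steps` evenly spaced slope values in
#' `[b_min, b_max]` (endpoints included), with fixed curvature `a`. Defaults
#' are the settings found adequate for 160x120 frames: a = 0.003,
#' b in \[-0.58, -0.14\], four b steps.
#'
#' @param a Curvature coefficient (rows per col^2).
#' @param b_min,b_max Slope range at column 0.
#' @param b_steps Number of slope values (>= 1).
#' @return Object of class `"scan_params"`.
#' @export
scan_params <- function(a = 0.003, b_min = -0.58, b_max = -0.14, b_steps = 4) {
  stopifnot(b_steps >= 1, b_min <= b_max)
  structure(list(a = a, b_min = b_min, b_max = b_max,
                 b_steps = as.integer(b_steps)),
            class = "scan_params")
}

#' 8-connected component labelling
#'
#' Connected components with 8-connectivity (diagonal neighbours connect),
#' the semantics the level detector assumes: a thin rasterized curve whose
#' slope exceeds 45 degrees steps diagonally and must remain one component.
#' Built on 4-connected labelling followed by union of labels that touch
#' diagonally.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Integer matrix of labels (0 = background).
#' @export
label_components <- function(mask) {
  l <- EBImage::bwlabel(as_binary(mask) * 1)
  n <- max(l)
  if (n <= 1) return(l)
  nr <- nrow(l); nc <- ncol(l)
  # diagonal neighbour label pairs (down-right and down-left)
  a1 <- l[-nr, -nc]; b1 <- l[-1, -1]
  a2 <- l[-nr, -1];  b2 <- l[-1, -nc]
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]),
                        cbind(a2[keep2], b2[keep2])))
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  out <- l
  out[l > 0] <- relabel[l[l > 0]]
  out
}

# rasterize row = a col^2 + b col + c over all columns (0-based), returning
# integer rows (rounded), NA outside the image
raster_curve <- function(a, b, c_, cols, rows) {
  col0 <- 0:(cols - 1)
  r <- round(a * col0^2 + b * col0 + c_)
  r[r < 0 | r > rows - 1] <- NA
  r
}

#' Scan quadratic curves over a mask to find the level component
#'
#' Labels the mask into connected components, rasterizes every scan curve
#' (each `c` in `0:(rows-1)` crossed with each of the `b_steps` slopes) and
#' counts, per component, the pixels intersected by a single curve. The
#' component achieving the maximum single-curve overlap is returned along
#' with the maximizing `(b, c)`. Ties are broken toward the smallest `c`
#' (topmost curve), then the smallest `b`.
#'
#' An empty mask — the valid state for an empty glass — yields a typed
#' [empty_result()] with reason `"no_level"` rather than an error. The same
#' signal is returned when no component reaches `min_overlap` intersection
#' pixels: a genuine level line spans a substantial fraction of the frame
#' width, whereas specular clutter intersects a scan curve in only a few
#' pixels, so an empty glass with reflections is still reported as empty.
#'
#' @param mask Logical or 0/1 matrix.
#' @param params A [scan_params()].
#' @param min_overlap Minimum accepted single-curve overlap in pixels;
#'   `NULL` (default) uses a quarter of the image width.
#' @return List of class `"level_scan"` with `component` (component id in the
#'   labelled mask), `overlap` (pixel count), `b`, `c`, and `labels` (the
#'   component labelling, reused downstream); or an [empty_result()].
#' @export
scan_curves <- function(mask, params = scan_params(), min_overlap = NULL) {
  check_mask(mask)
  m <- as_binary(mask)
  if (!any(m)) return(empty_result("no_level", "empty mask"))
  rows <- nrow(m); cols <- ncol(m)
  if (is.null(min_overlap)) min_overlap <- ceiling(cols / 4)
  labels <- label_components(m)
  bs <- if (params$b_steps == 1) {
    (params$b_min + params$b_max) / 2
  } else {
    seq(params$b_min, params$b_max, length.out = params$b_steps)
  }
  best <- list(component = NA_integer_, overlap = 0L,
               b = NA_real_, c = NA_real_)
  col_idx <- 0:(cols - 1)
  for (c_ in 0:(rows - 1)) {
    for (b in bs) {
      r <- raster_curve(params$a, b, c_, cols, rows)
      ok <- !is.na(r)
      if (!any(ok)) next
      lab <- labels[cbind(r[ok] + 1, col_idx[ok] + 1)]
      lab <- lab[lab > 0]
      if (length(lab) == 0) next
      tab <- tabulate(lab)
      comp <- which.max(tab)
      if (tab[comp] > best$overlap) {
        best <- list(component = comp, overlap = tab[comp], b = b, c = c_)
      }
    }
  }
  if (best$overlap < min_overlap) {
    return(empty_result("no_level", sprintf(
      "best single-curve overlap %d below the acceptance minimum %d",
      best$overlap, as.integer(min_overlap))))
  }
  best$labels <- labels
  structure(best, class = "level_scan")
}

#' @export
print.level_scan <- function(x, ...) {
  cat("Level scan: component ", x$component, ", overlap ", x$overlap,
      " px at (b = ", signif(x$b, 3), ", c = ", x$c, ")\n", sep = "")
  invisible(x)
}

#' Extract, prune, bridge and smooth the level arc
#'
#' Reduces the selected connected component to a single-valued row trace:
#' per column, vertical runs taller than `prune_width` are dropped (they are
#' attached clutter, not the thin level line) and the remaining pixels
#' collapse to their vertical centroid; interior columns left without pixels
#' are bridged by linear interpolation between their neighbours; finally the
#' trace is smoothed with a centered moving average (window shrinks at the
#' ends).
#'
#' @param mask Logical or 0/1 matrix (only used for its shape when `labels`
#'   is supplied via `scan`).
#' @param scan A `"level_scan"` from [scan_curves()], or a component id
#'   (in which case the mask is labelled here).
#' @param prune_width Maximum vertical run height kept, px.
#' @param smooth_window Moving-average window, px.
#' @return Object of class `"arc_segment"`: data frame with 0-based `col`
#'   and (fractional) `row`, one row per column of the component's span;
#'   attributes `component` and `overlap`. Returns an [empty_result()]
#'   (`"no_level"`) when pruning removes every column.
#' @export
extract_level_segment <- function(mask, scan, prune_width = 3,
                                  smooth_window = 5) {
  if (is_empty_result(scan)) return(scan)
  if (inherits(scan, "level_scan")) {
    labels <- scan$labels
    comp <- scan$component
    overlap <- scan$overlap
  } else {
    check_mask(mask)
    labels <- label_components(mask)
    comp <- as.integer(scan)
    overlap <- NA_integer_
  }
  if (!comp %in% labels) stop("component ", comp, " not present in mask")
  idx <- which(labels == comp, arr.ind = TRUE)
  pix <- data.frame(row = idx[, 1] - 1, col = idx[, 2] - 1)  # 0-based

  # per-column pruning of tall vertical runs, then centroid collapse
  trace <- vapply(split(pix$row, pix$col), function(rr) {
    rr <- sort(rr)
    run_id <- cumsum(c(1, diff(rr) > 1))
    keep <- unlist(lapply(split(rr, run_id),
                          function(run) if (length(run) <= prune_width) run else NULL))
    if (length(keep) == 0) NA_real_ else mean(keep)
  }, numeric(1))
  cols_present <- as.integer(names(trace))
  ok <- !is.na(trace)
  if (!any(ok)) return(empty_result("no_level", "all columns pruned away"))

  # bridge gaps across the full span by linear interpolation
  span <- seq(min(cols_present[ok]), max(cols_present[ok]))
  filled <- stats::approx(cols_present[ok], trace[ok], xout = span,
                          method = "linear", rule = 2)$y

  # centered moving average, window shrinking near the ends
  w <- max(1L, as.integer(smooth_window))
  half <- w %/% 2
  n <- length(filled)
  smoothed <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(filled[lo:hi])
  }, numeric(1))

  structure(data.frame(col = span, row = smoothed),
            class = c("arc_segment", "data.frame"),
            component = comp, overlap = overlap)
}

#' @export
print.arc_segment <- function(x, ...) {
  cat("Arc segment: ", nrow(x), " columns (", min(x$col), "-", max(x$col),
      "), rows ", round(min(x$row), 1), "-", round(max(x$row), 1), "\n",
      sep = "")
  invisible(x)
}
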