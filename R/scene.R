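# Synthetic scene generator: renders the image a rim-mounted camera sees when
# looking down into a conical glass — a bright elliptical arc where the liquid
# meets the wall, over a shaded background with specular clutter — together
# with exact ground truth for the rendered ellipse.

# Pinhole projection of the liquid plane. The camera sits on the rim at world
# position (camera_radius, 0, height) and looks toward the glass axis at a
# fixed declination below the horizontal. Returns the 3x3 homography mapping
# liquid-plane coordinates (s, t, 1) to homogeneous pixel coordinates
# (col*w, row*w, w), 0-based pixels, origin top-left.
scene_homography <- function(fill_level_mm, height_mm, camera_radius_mm,
                             declination_deg, focal_px, image_shape) {
  d <- declination_deg * pi / 180
  r0 <- (image_shape[1] - 1) / 2
  c0 <- (image_shape[2] - 1) / 2
  dz <- fill_level_mm - height_mm
  kz <- cos(d) * camera_radius_mm - sin(d) * dz
  ky <- sin(d) * camera_radius_mm + cos(d) * dz
  rbind(c(-c0 * cos(d), focal_px, c0 * kz),
        c(-r0 * cos(d) + focal_px * sin(d), 0, r0 * kz - focal_px * ky),
        c(-cos(d), 0, kz))
}

#' Render a synthetic glass-interior image
#'
#' Renders the scene the measurement pipeline assumes: the contact line of the
#' liquid with the glass wall, seen from a camera on the rim, appears as a
#' bright elliptical arc (the far side of the projected liquid circle). The
#' background carries a radial illumination gradient and a small number of
#' specular blobs mimicking reflections. The exact projected ellipse is
#' recorded as ground truth.
#'
#' As the fill level rises toward the rim the liquid surface approaches the
#' camera and its far contact line moves toward the horizon, i.e. the arc's
#' tangent row decreases (moves up) monotonically and the level in pixels
#' (`rows - y_top`) increases.
#'
#' @param glass A [glass_spec()].
#' @param fill_level_mm Liquid level in mm from the base; must lie in
#'   `[0, height_mm]`. A fill of 0 renders an empty glass: no arc.
#' @param image_shape `c(rows, cols)`, default `c(160, 120)`.
#' @param declination_deg Camera declination below the horizontal, degrees.
#' @param focal_px Pinhole focal length in pixels.
#' @param camera_radius_mm Distance of the camera from the glass axis;
#'   defaults to the wall radius at the rim.
#' @param n_specular Number of specular blobs.
#' @param seed Integer seed controlling blob placement (rendering is
#'   bit-reproducible for a fixed seed and parameters).
#' @return List with elements `image` (rows x cols matrix in \[0, 1\]) and
#'   `truth` (class `"scene_truth"`): `level_mm`, `arc_points` (matrix of
#'   0-based (col, row) pixels actually drawn), `ellipse_truth` (an
#'   `ellipse_fit`-like object for the exact projected ellipse, or NULL for an
#'   empty glass), `level_px`, `area_px2`.
#' @export
render_scene <- function(glass = default_glass(), fill_level_mm,
                         image_shape = c(160L, 120L),
                         declination_deg = 40, focal_px = 70,
                         camera_radius_mm = glass$radius_at(glass$height_mm),
                         n_specular = 2, seed = 1) {
  stopifnot(inherits(glass, "glass_spec"), length(image_shape) == 2,
            all(image_shape >= 8))
  if (fill_level_mm < 0 || fill_level_mm > glass$height_mm) {
    stop("fill_level_mm outside the glass: must be in [0, ", glass$height_mm, "]")
  }
  rows <- as.integer(image_shape[1]); cols <- as.integer(image_shape[2])

  # background: radial illumination gradient + specular clutter
  rr <- matrix(0:(rows - 1), rows, cols)
  cc <- matrix(0:(cols - 1), rows, cols, byrow = TRUE)
  dctr <- sqrt((rr - (rows - 1) / 2)^2 + (cc - (cols - 1) / 2)^2)
  img <- 0.55 - 0.30 * dctr / max(dctr)
  img <- with_seed(seed, {
    for (i in seq_len(n_specular)) {
      bc <- c(runif(1, 0, rows - 1), runif(1, 0, cols - 1))
      sg <- runif(1, 2, 5)
      img <- img + 0.35 * exp(-((rr - bc[1])^2 + (cc - bc[2])^2) / (2 * sg^2))
    }
    img
  })

  arc_points <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("col", "row")))
  ellipse_truth <- NULL
  level_px <- NA_real_
  area_px2 <- NA_real_

  if (fill_level_mm > 0) {
    r_l <- glass$radius_at(fill_level_mm)
    H <- scene_homography(fill_level_mm, glass$height_mm, camera_radius_mm,
                          declination_deg, focal_px, c(rows, cols))
    # exact projected ellipse: image of the circle s^2 + t^2 = r^2
    Q <- diag(c(1, 1, -r_l^2))
    Hi <- solve(H)
    Qi <- t(Hi) %*% Q %*% Hi
    Qi <- (Qi + t(Qi)) / 2
    ellipse_truth <- make_ellipse_fit(matrix_to_conic(Qi), "truth", NA_integer_)
    if (is_empty_result(ellipse_truth)) {
      stop("camera model did not produce an elliptical section; adjust geometry")
    }
    m <- measure_ellipse(ellipse_truth, c(rows, cols))
    level_px <- m$level_px
    area_px2 <- m$area_px2

    # draw the far half of the contact line (s < 0 side), 2 px wide
    theta <- seq(pi / 2, 3 * pi / 2, length.out = 2000)
    pw <- H %*% rbind(r_l * cos(theta), r_l * sin(theta), 1)
    ok <- pw[3, ] > 1e-9
    pc <- round(pw[1, ok] / pw[3, ok])
    pr <- floor(pw[2, ok] / pw[3, ok])
    # 2-px stroke straddling the continuous curve: centroid floor(r) + 0.5 is
    # an unbiased estimate of the true row for uniformly distributed fractions
    pts <- rbind(cbind(pc, pr), cbind(pc, pr + 1))
    keep <- pts[, 1] >= 0 & pts[, 1] <= cols - 1 &
            pts[, 2] >= 0 & pts[, 2] <= rows - 1
    pts <- unique(pts[keep, , drop = FALSE])
    if (nrow(pts) > 0) {
      img[cbind(pts[, 2] + 1, pts[, 1] + 1)] <- 0.95
      arc_points <- pts
      colnames(arc_points) <- c("col", "row")
    }
  }

  truth <- structure(list(level_mm = fill_level_mm, arc_points = arc_points,
                          ellipse_truth = ellipse_truth,
                          level_px = level_px, area_px2 = area_px2,
                          image_shape = c(rows, cols)),
                     class = "scene_truth")
  list(image = clamp01(img), truth = truth)
}

#' @export
print.scene_truth <- function(x, ...) {
  cat("Scene truth: level ", x$level_mm, " mm, ", nrow(x$arc_points),
      " arc pixels", sep = "")
  if (!is.na(x$level_px)) {
    cat(", level ", round(x$level_px, 2), " px, area ",
        round(x$area_px2, 1), " px^2", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Degrade an image with Gaussian and salt-and-pepper noise
#'
#' Additive zero-mean Gaussian noise of the given variance is applied first,
#' then a fraction `sp_density` of pixels (chosen independently) is replaced
#' by 0 or 1 with equal probability. Output is clamped to \[0, 1\].
#' Reproducible under a fixed seed; with both noise levels zero the input is
#' returned unchanged.
#'
#' @param image Numeric matrix with intensities in \[0, 1\].
#' @param gaussian_variance Variance of the additive Gaussian component
#'   (intensity squared units).
#' @param sp_density Expected fraction of salt-and-pepper pixels, in \[0, 1\].
#' @param seed Integer seed.
#' @return Degraded image, same shape.
#' @export
add_noise <- function(image, gaussian_variance = 0, sp_density = 0, seed = 1) {
  check_image(image)
  if (sp_density < 0 || sp_density > 1) stop("sp_density must lie in [0, 1]")
  if (gaussian_variance < 0) stop("gaussian_variance must be >= 0")
  if (gaussian_variance == 0 && sp_density == 0) return(image)
  n <- length(image)
  with_seed(seed, {
    out <- image
    if (gaussian_variance > 0) {
      out <- out + stats::rnorm(n, 0, sqrt(gaussian_variance))
    }
    if (sp_density > 0) {
      hit <- stats::runif(n) < sp_density
      val <- ifelse(stats::runif(n) < 0.5, 0, 1)
      out[hit] <- val[hit]
    }
    matrix(clamp01(out), nrow(image), ncol(image))
  })
}

## ---- image and scene I/O ----------------------------------------------------

#' Read an image as a grayscale matrix
#'
#' PNG is read with the png package; other formats (JPEG, TIFF) through
#' EBImage. Color images are averaged over channels. The result is a
#' rows x cols matrix in \[0, 1\], row 1 at the top.
#'
#' @param path Image file path.
#' @return Numeric matrix.
#' @export
read_gray <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                        c(1, 2), mean)
    return(clamp01(a))
  }
  a <- EBImage::imageData(EBImage::channel(EBImage::readImage(path), "gray"))
  if (length(dim(a)) == 3) a <- a[, , 1]
  clamp01(t(a))  # EBImage stores (x, y); transpose to (row, col)
}

#' Write a grayscale matrix as an 8-bit PNG
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param path Output path (PNG).
#' @export
write_gray <- function(image, path) {
  check_image(image)
  png::writePNG(image, path)
  invisible(path)
}

#' Write a rendered scene and its ground-truth sidecar
#'
#' Writes `<name>.png` (8-bit grayscale) and `<name>.json` holding the scene
#' truth (level, measurements, ellipse parameters, arc pixels) to `dir`.
#'
#' @param scene A list as returned by [render_scene()].
#' @param dir Output directory (created if needed).
#' @param name File stem.
#' @return Invisibly, the paths written.
#' @export
write_scene <- function(scene, dir, name) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  png_path <- file.path(dir, paste0(name, ".png"))
  json_path <- file.path(dir, paste0(name, ".json"))
  write_gray(scene$image, png_path)
  tr <- scene$truth
  payload <- list(level_mm = tr$level_mm, level_px = tr$level_px,
                  area_px2 = tr$area_px2, image_shape = tr$image_shape,
                  arc_points = tr$arc_points)
  if (!is.null(tr$ellipse_truth) && !is_empty_result(tr$ellipse_truth)) {
    payload$ellipse <- list(center = tr$ellipse_truth$center,
                            semi_major = tr$ellipse_truth$semi_major,
                            semi_minor = tr$ellipse_truth$semi_minor,
                            tilt = tr$ellipse_truth$tilt)
  }
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(png_path, json_path))
}
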