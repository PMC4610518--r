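test_that("mirror completion doubles the arc and respects symmetry", {
  arc <- data.frame(col = 10:40,
                    row = 0.01 * ((10:40) - 25)^2 + 30)  # symmetric parabola
  pts <- mirror_segment(arc, bottom_offset = 20, image_shape = c(160, 120))
  expect_equal(nrow(pts), 2 * nrow(arc))
  # copy bottom sits exactly bottom_offset rows above the bottom edge
  expect_equal(max(pts[, "y"]), 159 - 20)
  # symmetric about a horizontal midline between arc top and copy bottom
  mid <- (min(pts[, "y"]) + max(pts[, "y"])) / 2
  reflected <- cbind(pts[, "x"], 2 * mid - pts[, "y"])
  expect_equal(sort(round(pts[, "y"], 9)), sort(round(reflected[, 2], 9)))
  expect_setequal(round(pts[, "x"], 9), round(reflected[, 1], 9))

  expect_error(mirror_segment(arc, bottom_offset = 160, c(160, 120)),
               "bottom_offset")
  tall_arc <- data.frame(col = 10:40, row = seq(30, 90, length.out = 31))
  expect_error(mirror_segment(tall_arc, bottom_offset = 155, c(160, 120)),
               "above the image top")
})

test_that("exact points on circles and tilted ellipses are recovered", {
  for (method in c("ls_conic", "direct", "taubin")) {
    circ <- fit_ellipse(ellipse_points(c(60, 80), 10, 10, n = 8), method)
    expect_s3_class(circ, "ellipse_fit")
    expect_equal(circ$center, c(60, 80), tolerance = 1e-6)
    expect_equal(circ$semi_major, 10, tolerance = 1e-6)
    expect_equal(circ$semi_minor, 10, tolerance = 1e-6)

    ell <- fit_ellipse(ellipse_points(c(55, 70), 30, 12, 0.4, n = 12), method)
    expect_equal(ell$center, c(55, 70), tolerance = 1e-6)
    expect_equal(ell$semi_major, 30, tolerance = 1e-6)
    expect_equal(ell$semi_minor, 12, tolerance = 1e-6)
    expect_equal(ell$tilt, 0.4, tolerance = 1e-6)
  }
})

test_that("degenerate inputs yield the typed no-ellipse outcome", {
  collinear <- cbind(1:5, 2 * (1:5) + 3)
  for (method in c("ls_conic", "direct", "taubin")) {
    out <- fit_ellipse(collinear, method)
    expect_true(is_empty_result(out))
    expect_equal(out$reason, "no_ellipse")
  }
  expect_true(is_empty_result(fit_ellipse(cbind(1:4, 1:4))))  # < 5 points
})

test_that("all three fitters agree within 1% on well-conditioned arcs", {
  pts <- ellipse_points(c(60, 80), 40, 25, 0.3, n = 200,
                        theta = seq(0.2, pi, length.out = 200))
  fits <- lapply(c("ls_conic", "direct", "taubin"), function(m)
    fit_ellipse(pts, m))
  for (i in 2:3) {
    expect_equal(fits[[i]]$semi_major, fits[[1]]$semi_major, tolerance = 0.01)
    expect_equal(fits[[i]]$semi_minor, fits[[1]]$semi_minor, tolerance = 0.01)
    expect_equal(fits[[i]]$center, fits[[1]]$center, tolerance = 0.01)
  }
})

test_that("parameter recovery degrades gracefully under 0.5 px jitter", {
  set.seed(31)
  for (rep in 1:5) {
    center <- c(runif(1, 50, 70), runif(1, 60, 100))
    a <- runif(1, 30, 45); b <- runif(1, 15, 25); tilt <- runif(1, -0.5, 0.5)
    pts <- ellipse_points(center, a, b, tilt, n = 400)
    pts_j <- pts + matrix(rnorm(length(pts), 0, 0.5), ncol = 2)
    fit <- fit_ellipse(pts_j, "ls_conic")
    expect_equal(fit$center, center, tolerance = 0.02 * max(a, b))
    expect_equal(fit$semi_major, a, tolerance = 0.02 * a)
    expect_equal(fit$semi_minor, b, tolerance = 0.02 * b)
  }
})

test_that("fits are equivariant under translation and rotation", {
  pts <- ellipse_points(c(0, 0), 20, 9, 0.25, n = 40)
  base <- fit_ellipse(pts, "ls_conic")

  shifted <- sweep(pts, 2, c(13.5, -7.25), "+")
  fs <- fit_ellipse(shifted, "ls_conic")
  expect_equal(fs$center, base$center + c(13.5, -7.25), tolerance = 1e-6)
  expect_equal(fs$semi_major, base$semi_major, tolerance = 1e-6)
  expect_equal(fs$semi_minor, base$semi_minor, tolerance = 1e-6)
  expect_equal(fs$tilt, base$tilt, tolerance = 1e-6)

  ang <- 0.3
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  rotated <- pts %*% t(R)
  fr <- fit_ellipse(rotated, "ls_conic")
  expect_equal(as.vector(R %*% base$center), fr$center, tolerance = 1e-6)
  expect_equal(fr$semi_major, base$semi_major, tolerance = 1e-6)
  expect_equal(fr$tilt, base$tilt + ang, tolerance = 1e-6)
})

test_that("measurements follow the tangent-line geometry", {
  # axis-aligned: cy = 100, vertical semi-axis 20, rows = 160
  e <- fit_ellipse(ellipse_points(c(60, 100), 35, 20, 0, n = 24))
  m <- measure_ellipse(e, c(160, 120))
  expect_equal(m$y_top, 80, tolerance = 1e-6)
  expect_equal(m$level_px, 80, tolerance = 1e-6)
  expect_equal(m$area_px2, pi * 35 * 20, tolerance = 1e-6)

  circ <- fit_ellipse(ellipse_points(c(60, 80), 15, 15, n = 12))
  expect_equal(measure_ellipse(circ, c(160, 120))$area_px2, pi * 15^2,
               tolerance = 1e-6)
})

test_that("vertical extent of a tilted ellipse matches a parametric oracle", {
  e <- fit_ellipse(ellipse_points(c(60, 90), 33, 14, 0.7, n = 64))
  m <- measure_ellipse(e, c(160, 120))
  th <- seq(0, 2 * pi, length.out = 1e6)
  y <- 90 + 33 * cos(th) * sin(0.7) + 14 * sin(th) * cos(0.7)
  expect_equal(m$y_top, min(y), tolerance = 1e-3)
})

test_that("area is invariant under tilt", {
  areas <- vapply(c(0, 0.3, 0.8, 1.3), function(tl) {
    e <- fit_ellipse(ellipse_points(c(60, 80), 28, 11, tl, n = 32))
    measure_ellipse(e, c(160, 120))$area_px2
  }, numeric(1))
  expect_equal(areas, rep(pi * 28 * 11, 4), tolerance = 1e-9)
})

test_that("fixture measurements are inversely ordered as recorded", {
  tab <- table2_pairs()
  # per fill level: derived level in px rises while derived area falls
  lvl <- aggregate(cbind(level_px, area_px2) ~ level_mm, tab, mean)
  expect_true(all(diff(lvl$level_px) > 0))
  expect_true(all(diff(lvl$area_px2) < 0))
})
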