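test_that("the bundled calibration table loads with its recorded flags", {
  tab <- read_calibration_table()
  expect_s3_class(tab, "calibration_table")
  expect_equal(nrow(tab), 18)
  expect_equal(tab$image[tab$outlier], c(2, 16, 17, 18))
  expect_equal(sum(!tab$outlier), 14)
  # recorded volumes pair with recorded diameters per level
  expect_equal(unique(tab$calc_vol_ml[tab$level_mm == 40]), 139)
})

test_that("quadratic level fit reproduces exact data and its statistics identity", {
  x <- c(20, 45, 80, 110, 150)
  y <- 0.002 * x^2 - 0.05 * x + 12
  fit <- fit_level_model(x, y)
  expect_equal(coef(fit), c(p1 = 0.002, p2 = -0.05, p3 = 12), tolerance = 1e-9)
  expect_equal(fit$stats$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$stats$std_error, 0, tolerance = 1e-9)

  # R^2 / std_error consistency: se^2 * dof = (1 - R^2) * SS_tot
  tab <- table2_pairs()
  f2 <- fit_level_model(tab$level_px, tab$level_mm)
  ss_tot <- sum((tab$level_mm - mean(tab$level_mm))^2)
  expect_equal(f2$stats$std_error^2 * f2$stats$dof,
               (1 - f2$stats$r_squared) * ss_tot, tolerance = 1e-9)

  expect_error(fit_level_model(rep(5, 6), 1:6), "rank-deficient")
  expect_error(fit_level_model(1:3, 1:3), "at least 4")
})

test_that("level fit is scale-equivariant in the pixel axis", {
  tab <- table2_pairs()
  f1 <- fit_level_model(tab$level_px, tab$level_mm)
  s <- 2.5
  f2 <- fit_level_model(s * tab$level_px, tab$level_mm)
  expect_equal(f2$p1, f1$p1 / s^2, tolerance = 1e-9)
  expect_equal(f2$p2, f1$p2 / s, tolerance = 1e-9)
  expect_equal(f2$p3, f1$p3, tolerance = 1e-9)
})

test_that("two-term exponential fit recovers exact generating models", {
  x <- seq(5000, 45000, length.out = 12)
  y <- 3.7e3 * exp(2.5e-6 * x) - 3.6e3 * exp(-2.4e-4 * x)
  fit <- fit_area_model(x, y)
  expect_equal(fit$stats$r_squared, 1, tolerance = 1e-6)
  expect_equal(predict(fit, 20000), 3.7e3 * exp(0.05) - 3.6e3 * exp(-4.8),
               tolerance = 1e-3)
  expect_error(fit_area_model(1:3, 1:3), "at least 5")
})

test_that("simulated calibration tables recover coefficients within 3 SE", {
  # parameter recovery for the quadratic under Gaussian noise, seeded
  set.seed(7)
  hits <- 0L; runs <- 20L
  for (r in seq_len(runs)) {
    x <- runif(14, 40, 150)
    y <- 1.7e-3 * x^2 + 4.7e-2 * x + 15 + rnorm(14, 0, 1.5)
    fit <- fit_level_model(x, y)
    se <- sqrt(diag(stats::vcov(fit$lm)))[c(3, 2, 1)]
    ok <- abs(coef(fit) - c(1.7e-3, 4.7e-2, 15)) < 3 * se
    hits <- hits + all(ok)
  }
  expect_gte(hits, 0.9 * runs)
})

test_that("prediction helpers evaluate published coefficient sets", {
  eq1 <- poly2_model(p1 = 1.68e-3, p2 = 4.71e-2, p3 = 15.4)
  expect_equal(predict_level(eq1, 0), 15.4)                   # intercept
  expect_equal(predict_level(eq1, 44), 20.73, tolerance = 1e-3)
  expect_equal(predict_level(eq1, 146), 58.09, tolerance = 1e-3)
  expect_error(predict_level(eq1, NA), "finite")

  # published fast-rate coefficient read as 1e-6 scale (the printed 1e+6
  # overflows at any observed area)
  eq2 <- exp2_model(a = 3.67e3, b = 2.51e-6, c = -3.65e3, d = -2.43e-4)
  expect_equal(predict_area(eq2, 8215), 3250.7, tolerance = 0.1)
  expect_equal(predict_area(eq2, 41572), 4073.5, tolerance = 0.1)
  # close to the ground-truth sections of the fixture glass
  expect_equal(predict_area(eq2, 8215), pi * 32^2, tolerance = 0.015)
  expect_equal(predict_area(eq2, 41572), pi * 36^2, tolerance = 0.005)
  expect_error(predict_area(eq2, Inf), "finite")
})

test_that("refitting the fixture table reproduces the published coefficients", {
  tab <- table2_pairs()
  lv <- fit_level_model(tab$level_px, tab$level_mm)
  expect_equal(coef(lv), c(p1 = 1.68e-3, p2 = 4.71e-2, p3 = 15.4),
               tolerance = 0.03)
  ar <- fit_area_model(tab$area_px2, pi * (tab$diameter_mm / 2)^2)
  expect_equal(ar$a, 3.67e3, tolerance = 0.01)
  expect_equal(ar$b, 2.51e-6, tolerance = 0.01)
  expect_equal(ar$c, -3.65e3, tolerance = 0.01)
  expect_equal(ar$d, -2.43e-4, tolerance = 0.01)
})

test_that("iterated robust flagging finds exactly the recorded outliers", {
  tab <- read_calibration_table()
  flags <- flag_outliers(tab, k = 2.5)
  expect_equal(tab$image[flags], c(2, 16, 17, 18))
})

test_that("clean tables yield no flags; gross corruption is flagged", {
  x <- seq(40, 150, length.out = 12)
  area_x <- seq(8000, 45000, length.out = 12)
  clean <- data.frame(
    image = 1:12,
    level_mm = 1.7e-3 * x^2 + 4.7e-2 * x + 15,
    diameter_mm = 2 * sqrt((3.7e3 * exp(2.5e-6 * area_x) -
                            3.6e3 * exp(-2.4e-4 * area_x)) / pi),
    calc_vol_ml = NA, level_px = x, area_px2 = area_x,
    derived_vol_ml = NA, outlier = FALSE)
  expect_equal(sum(flag_outliers(clean, k = 2.5)), 0)

  bad <- clean
  bad$level_px[6] <- bad$level_px[6] * 10
  flags <- flag_outliers(bad, k = 2.5)
  expect_true(flags[6])
  expect_equal(sum(flags), 1)
})
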