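exact_line_points <- function(slope = 2, intercept = 0.1, n = 6) {
  x <- seq(0.05, 0.5, length.out = n)
  data.frame(x = x, y = intercept + slope * x, protein_id = "toy")
}

test_that("exact lines give |r| = 1 and exact coefficients", {
  cal <- fit_calibration(exact_line_points(), "npf")
  expect_equal(cal$slope, 2, tolerance = 1e-12)
  expect_equal(cal$intercept, 0.1, tolerance = 1e-12)
  expect_equal(cal$pearson_r, 1, tolerance = 1e-12)

  anti <- exact_line_points()
  anti$y <- rev(anti$y)  # equally spaced x: reversal is an exact falling line
  expect_equal(fit_calibration(anti, "npf")$pearson_r, -1, tolerance = 1e-12)

  flat <- exact_line_points()
  flat$x <- 0.3
  expect_error(fit_calibration(flat, "npf"), "zero variance")
})

test_that("coefficients match the closed-form normal equations", {
  set.seed(11)
  pts <- data.frame(x = runif(6), protein_id = "toy")
  pts$y <- 0.2 + 1.4 * pts$x + rnorm(6, sd = 0.05)
  pts$y <- pmax(pts$y, 0)
  cal <- fit_calibration(pts, "npf")
  X <- cbind(1, pts$x)
  beta <- solve(crossprod(X), crossprod(X, pts$y))
  expect_equal(cal$intercept, beta[1], tolerance = 1e-10)
  expect_equal(cal$slope, beta[2], tolerance = 1e-10)
  expect_equal(cal$pearson_r, cor(pts$x, pts$y), tolerance = 1e-12)
})

test_that("prediction applies the line, clips at zero, scales by GXG", {
  cal <- fit_calibration(exact_line_points(2, 0.1), "npf")
  ref <- c(TRP = 220, ALA = 66)
  nd <- data.frame(x = c(0.2, 0), resname = c("TRP", "ALA"))
  pred <- predict_sasa(cal, nd, ref)
  expect_equal(pred$predicted_fractional, c(0.5, 0.1))  # 2*0.2+0.1; intercept at x=0
  expect_equal(pred$predicted_sasa, c(0.5 * 220, 0.1 * 66))

  # OLS property: prediction at the training mean equals the mean response
  pts <- exact_line_points()
  pts$y <- pts$y + c(0.01, -0.02, 0.03, 0, -0.01, -0.01)
  cal2 <- fit_calibration(pts, "npf")
  at_mean <- predict_sasa(cal2, data.frame(x = mean(pts$x), resname = "TRP"), ref)
  expect_equal(at_mean$predicted_fractional, mean(pts$y), tolerance = 1e-12)

  neg <- fit_calibration(data.frame(x = 1:4 / 4, y = c(0.5, 0.4, 0.2, 0.1)), "npf")
  expect_warning(out <- predict_sasa(neg, data.frame(x = 2, resname = "TRP"), ref),
                 "clipped")
  expect_equal(out$predicted_fractional, 0)
  expect_error(predict_sasa(cal, data.frame(x = 0.1, resname = "GLY"), ref),
               "glycine")
})

test_that("jackknife models coincide with the full fit on exact-line data", {
  pts <- exact_line_points(n = 5)
  jk <- jackknife(pts, "npf")
  expect_length(jk$models, 5L)
  full <- fit_calibration(pts, "npf")
  for (m in jk$models) {
    expect_equal(m$slope, full$slope, tolerance = 1e-10)
    expect_equal(m$intercept, full$intercept, tolerance = 1e-10)
  }
  expect_equal(diff(jk$summary$slope_range), 0, tolerance = 1e-10)
})

test_that("leave-one-out predictions match a brute-force refit loop", {
  set.seed(5)
  pts <- data.frame(x = runif(8), protein_id = "toy")
  pts$y <- pmax(0, 0.1 + 0.9 * pts$x + rnorm(8, sd = 0.08))
  jk <- jackknife(pts, "ratio")
  expect_length(jk$models, 8L)
  for (i in seq_len(8)) {
    fit <- lm(y ~ x, data = pts[-i, ])
    expect_equal(jk$loo$predicted[i],
                 unname(predict(fit, pts[i, , drop = FALSE])),
                 tolerance = 1e-12)
  }
})

test_that("prediction evaluation reports RMSD and R-squared against y = x", {
  perfect <- data.frame(predicted_sasa = c(10, 50, 90),
                        reference_sasa = c(10, 50, 90))
  ev <- evaluate_predictions(perfect)
  expect_equal(ev$rmsd, 0)
  expect_equal(ev$r_squared, 1)

  offset <- data.frame(predicted_sasa = c(15, 55, 95),
                       reference_sasa = c(10, 50, 90))
  expect_equal(evaluate_predictions(offset)$rmsd, 5)

  # hand-computed 5-pair example
  tab <- data.frame(predicted_sasa = c(12, 18, 35, 60, 95),
                    reference_sasa = c(10, 25, 30, 55, 100))
  ev2 <- evaluate_predictions(tab)
  resid <- tab$predicted_sasa - tab$reference_sasa
  expect_equal(ev2$rmsd, sqrt(mean(resid^2)))
  expect_equal(ev2$r_squared,
               1 - sum(resid^2) / sum((tab$reference_sasa - mean(tab$reference_sasa))^2))
  expect_equal(ev2$pearson_r, cor(tab$predicted_sasa, tab$reference_sasa))
  expect_error(evaluate_predictions(data.frame(predicted_sasa = 1:3)), "reference")
})

test_that("redundant training data leaves the calibration unchanged", {
  set.seed(3)
  pts <- data.frame(x = runif(10), protein_id = "myo")
  pts$y <- pmax(0, 0.05 + 1.1 * pts$x + rnorm(10, sd = 0.05))
  base <- fit_calibration(pts, "npf")
  doubled <- fit_calibration(rbind(pts, pts), "npf")
  expect_equal(doubled$slope, base$slope, tolerance = 1e-12)
  expect_equal(doubled$intercept, base$intercept, tolerance = 1e-12)
})

test_that("calibration models persist to structured text and back", {
  cal <- fit_calibration(exact_line_points(), "ratio")
  path <- withr::local_tempfile(fileext = ".txt")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_equal(back$slope, cal$slope)
  expect_equal(back$intercept, cal$intercept)
  expect_equal(back$mode, "ratio")
  expect_equal(back$training_proteins, cal$training_proteins)
})
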