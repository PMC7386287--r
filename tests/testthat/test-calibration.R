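test_that("exact lines are fitted exactly", {
  x <- c(1, 2, 3, 4)
  fit <- fit_linear(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_linear(rep(2, 4), 1:4), "singular")
  expect_error(fit_linear(1:2, 1:2), "at least 3")
})

test_that("OLS agrees with an independent brute-force SSE minimizer", {
  set.seed(31)
  for (i in 1:4) {
    n <- sample(4:10, 1)
    x <- sort(runif(n, 0, 20))
    y <- 0.007 * x + 0.001 + rnorm(n, 0, 0.002)
    fit <- fit_linear(x, y)
    bf <- brute_force_ols(x, y)
    expect_equal(fit$slope, bf$slope, tolerance = 1e-6)
    expect_equal(fit$intercept, bf$intercept, tolerance = 1e-6)
  }
})

test_that("linear-interval detection keeps linear data and trims saturation", {
  x <- seq(1, 20)
  lin <- data.frame(chl = x, gpi_final = 0.007 * x + 0.001)
  res <- find_linear_interval(lin)
  expect_equal(nrow(res$points), 20L)
  expect_equal(res$upper_limit_chl, 20)

  # noise-free saturating response: everything past the breakpoint is dropped
  cfg <- assay_config(noise_sd_gpi = 0, conc_grid = seq(1, 25, by = 1),
                      breakpoint_chl = 16)
  sat <- data.frame(chl = cfg$conc_grid,
                    gpi_final = assay_mean_response(cfg$conc_grid, cfg))
  res2 <- find_linear_interval(sat)
  expect_equal(res2$upper_limit_chl, 16)
  expect_equal(res2$fit$r_squared, 1, tolerance = 1e-9)
  # prefix structure: retained concentrations are the smallest k
  expect_equal(res2$points$chl, seq(1, 16))

  expect_error(find_linear_interval(lin[1:2, ]), "at least 3")
  expect_error(
    find_linear_interval(data.frame(chl = c(1, 1, 1, 2),
                                    gpi_final = c(0, 0, 0, 1))),
    "distinct"
  )
})

test_that("interval upper limit lies on the fitted line", {
  set.seed(32)
  sim <- simulate_calibration_dataset(assay_config(), seed = 7)
  res <- find_linear_interval(sim$points)
  expect_gte(nrow(res$points), 3L)
  expect_equal(res$upper_limit_gpi,
               res$fit$slope * res$upper_limit_chl + res$fit$intercept,
               tolerance = 1e-12)
})

test_that("confidence bands match the closed-form pointwise formula", {
  x <- c(1, 3, 5, 8, 13)
  y <- c(0.010, 0.024, 0.034, 0.058, 0.089)
  fit <- fit_linear(x, y)
  grid <- seq(0, 15, by = 0.5)
  band <- confidence_band(fit, grid, level = 0.95)

  # independent evaluation from first principles
  n <- length(x)
  xbar <- mean(x)
  ssx <- sum((x - xbar)^2)
  b <- sum((x - xbar) * (y - mean(y))) / ssx
  a <- mean(y) - b * xbar
  s <- sqrt(sum((y - (a + b * x))^2) / (n - 2))
  tq <- qt(0.975, n - 2)
  hw <- tq * s * sqrt(1 / n + (grid - xbar)^2 / ssx)
  expect_equal(band$fit, a + b * grid, tolerance = 1e-10)
  expect_equal(band$half_width, hw, tolerance = 1e-10)

  # at the mean of x the half width collapses to t * s / sqrt(n)
  at_mean <- confidence_band(fit, xbar)
  expect_equal(at_mean$half_width, tq * s / sqrt(n), tolerance = 1e-10)

  # width grows monotonically away from the mean
  left <- band$half_width[band$x <= xbar]
  right <- band$half_width[band$x >= xbar]
  expect_true(all(diff(left) <= 1e-15))
  expect_true(all(diff(right) >= -1e-15))

  expect_error(confidence_band(fit, numeric(0)), "non-empty")
  expect_error(confidence_band(fit, 1, level = 1.2), "level")
})

test_that("limit of blank follows the mean + 1.645 SD convention", {
  expect_equal(limit_of_blank(c(0, 0, 0)), 0)
  blanks <- c(0, 0.001, -0.001, 0.002, -0.002)
  expect_equal(limit_of_blank(blanks),
               mean(blanks) + 1.645 * sd(blanks), tolerance = 1e-12)
  expect_equal(limit_of_blank(blanks), 0.002601, tolerance = 1e-4)
  expect_error(limit_of_blank(c(0, 0.001)), "at least 3")
})

test_that("limit of detection combines blank and low-concentration spread", {
  curve <- calibration_curve(slope = 0.00694, intercept = 0)
  low <- c(-0.001, 0, 0.001)  # SD exactly 0.001
  lod <- limit_of_detection(0.0026, low, curve)
  expect_equal(lod$lod_gpi, 0.0026 + 1.645 * 0.001, tolerance = 1e-12)
  expect_equal(lod$lod_conc, (0.0026 + 0.001645) / 0.00694, tolerance = 1e-6)

  # degenerate: no spread, zero LoB, negative intercept floors at 0
  curve2 <- calibration_curve(slope = 0.01, intercept = 0.002)
  lod2 <- limit_of_detection(0, c(0.1, 0.1, 0.1), curve2)
  expect_equal(lod2$lod_conc, 0)

  bad <- calibration_curve(slope = 1, intercept = 0)
  bad$slope <- -1
  expect_error(limit_of_detection(0.001, low, bad), "slope")
})

test_that("LoD recovery: simulated assays designed for LoD 0.12 ug/ml", {
  # With triplicate-mean blanks (SD sigma/sqrt(3)) and per-photo low-conc
  # replicates (SD sigma), the expected LoD is
  # 1.645 * sigma * (1/sqrt(3) + 1) / slope; sigma chosen so that is 0.12.
  slope <- 0.00694
  sigma <- 0.12 * slope / (1.645 * (1 / sqrt(3) + 1))
  curve <- calibration_curve(slope = slope, intercept = 0)
  set.seed(33)
  lods <- replicate(200, {
    blanks <- rowMeans(matrix(rnorm(30, 0, sigma), nrow = 10))
    low <- rnorm(3, 0.3 * slope, sigma)
    limit_of_detection(limit_of_blank(blanks), low, curve)$lod_conc
  })
  expect_lt(abs(mean(lods) - 0.12) / 0.12, 0.25)
})

test_that("percent RSD back-predicts concentrations per replicate", {
  curve <- calibration_curve(slope = 0.01, intercept = 0.001)
  # replicates mapping exactly to predictions {9.5, 10.0, 10.5} -> 5.0 %RSD
  pts <- data.frame(
    chl = 10, gpi_final = 0.101,
    gpi_rep1 = 0.001 + 0.095, gpi_rep2 = 0.001 + 0.100, gpi_rep3 = 0.001 + 0.105
  )
  expect_equal(percent_rsd(pts, curve), 100 * sd(c(9.5, 10, 10.5)) / 10,
               tolerance = 1e-9)

  same <- data.frame(chl = 5, gpi_final = 0.051,
                     gpi_rep1 = 0.051, gpi_rep2 = 0.051, gpi_rep3 = 0.051)
  expect_equal(percent_rsd(same, curve), 0)

  neg <- data.frame(chl = c(5, 1), gpi_final = c(0.051, -0.05),
                    gpi_rep1 = c(0.051, -0.05), gpi_rep2 = c(0.051, -0.05),
                    gpi_rep3 = c(0.051, -0.05))
  expect_warning(r <- percent_rsd(neg, curve), "non-positive")
  expect_equal(r, 0)
})

test_that("inverse prediction is the exact inverse and flags ranges", {
  curve <- calibration_curve(slope = 0.00694, intercept = 0.000799,
                             upper_limit_chl = 16, lod_conc = 0.12)
  set.seed(34)
  x <- runif(50, 0, 16)
  pred <- predict_chlorophyll(curve, 0.00694 * x + 0.000799)
  expect_true(all(abs(pred$chl - x) < 1e-9))

  one <- predict_chlorophyll(curve, 0.0702)
  expect_equal(one$chl, (0.0702 - 0.000799) / 0.00694, tolerance = 1e-9)
  expect_equal(round(one$chl, 2), 10.00)
  expect_equal(one$status, "ok")

  expect_equal(predict_chlorophyll(curve, 0.000799)$status, "below_LoD")
  expect_equal(predict_chlorophyll(curve, 0.000799)$chl, 0)
  expect_equal(predict_chlorophyll(curve, 0.126)$status, "dilute_sample")
  expect_equal(predict_chlorophyll(curve, curve$upper_limit_gpi)$status, "ok")

  flat <- calibration_curve(slope = 1, intercept = 0)
  flat$slope <- 0
  expect_error(predict_chlorophyll(flat, 0.05), "slope")
})

test_that("build_standard_curve composes fit, limits and precision", {
  # noise-free linear data with triplicate replicates
  x <- seq(0.5, 16, length.out = 12)
  gpi <- 0.00694 * x
  pts <- data.frame(sample_id = paste0("s", seq_along(x)), chl = x,
                    gpi_final = gpi, gpi_rep1 = gpi, gpi_rep2 = gpi,
                    gpi_rep3 = gpi)
  cv <- build_standard_curve(pts, blanks = c(0, 0, 0, 0))
  expect_s3_class(cv, "calibration_curve")
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
  expect_equal(cv$percent_rsd, 0)
  expect_equal(cv$lob_gpi, 0)
  expect_equal(cv$lod_conc, 0)
  expect_equal(cv$upper_limit_chl, 16)
  expect_true(cv$lod_conc >= cv$lob_conc)

  # noisy curve keeps the LoB/LoD ordering invariant
  sim <- simulate_calibration_dataset(assay_config(), seed = 9)
  cv2 <- build_standard_curve(sim$points, sim$blanks)
  expect_true(cv2$lod_conc >= cv2$lob_conc)
  expect_gte(cv2$lob_conc, 0)
  expect_equal(cv2$upper_limit_gpi,
               cv2$slope * cv2$upper_limit_chl + cv2$intercept,
               tolerance = 1e-12)
})
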