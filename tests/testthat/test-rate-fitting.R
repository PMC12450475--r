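test_that("noiseless series are inverted up to integer-lesion rounding", {
  cat <- simulate_gene_catalog(1500, seed = 21)
  for (true_r in c(200, 2000)) {
    ser <- simulate_loss_series(cat, rate = true_r, ages_weeks = c(8, 14, 20),
                                noise_sd = 0, seed = 1)
    fit <- calibrate_rate(cat, ser)
    # rounding bound: half a lesion over the calibration interval
    expect_lt(abs(fit$r - true_r), 1 / (8 * 7) + true_r * 1e-3)
    v <- fit$validation
    expect_lt(max(v$abs_error_pct), 0.1)
  }
})

test_that("zero observed loss calibrates to rate zero", {
  cat <- toy_catalog()
  ser <- tibble::tibble(age_weeks = c(5, 10), loss_pct = c(0, 0),
                        sem_pct = c(0, 0))
  fit <- calibrate_rate(cat, ser)
  expect_equal(fit$r, 0)
})

test_that("calibration conventions: first-point vs last-point (wildtype style)", {
  cat <- simulate_gene_catalog(1500, seed = 22)
  ser <- simulate_loss_series(cat, rate = 62, ages_weeks = c(7, 104),
                              t0_weeks = 7, noise_sd = 0, seed = 2)
  # calibrate on the last point, predict the first (assumed lesion-free)
  fit <- calibrate_rate(cat, ser, calibrate_on = "last")
  expect_equal(fit$t0_weeks, 7)
  expect_equal(fit$r, 62, tolerance = 0.01)
  expect_equal(fit$validation$role, c("validation", "calibration"))
  # deficient convention counts lesions from birth
  fit2 <- calibrate_rate(cat, simulate_loss_series(
    cat, 2000, c(8, 14), noise_sd = 0, seed = 3), calibrate_on = "first")
  expect_equal(fit2$t0_weeks, 0)
})

test_that("monotone consistency: larger observed loss never fits a smaller rate", {
  cat <- simulate_gene_catalog(800, seed = 23)
  losses <- c(5, 10, 20, 40, 60)
  rates <- sapply(losses, function(lp) {
    ser <- tibble::tibble(age_weeks = c(10, 20),
                          loss_pct = c(lp, min(lp * 1.5, 99)),
                          sem_pct = c(1, 1))
    calibrate_rate(cat, ser)$r
  })
  expect_true(all(diff(rates) > 0))
})

test_that("unreachable losses and degenerate intervals error", {
  cat <- toy_catalog()
  ser <- tibble::tibble(age_weeks = c(5, 10), loss_pct = c(100, 100),
                        sem_pct = c(0, 0))
  expect_error(calibrate_rate(cat, ser), "asymptote")
  expect_error(
    calibrate_rate(cat, tibble::tibble(age_weeks = c(0, 5),
                                       loss_pct = c(10, 20),
                                       sem_pct = c(0, 0)),
                   calibrate_on = "first", t0_weeks = 0),
    "dt = 0")
})

test_that("replicate catalogs give a rate spread and validation errors", {
  base <- simulate_gene_catalog(800, seed = 24)
  reps <- replicate_catalogs(base, n = 3, expr_jitter = 0.15, seed = 5)
  ser <- simulate_loss_series(base, rate = 1500, ages_weeks = c(8, 16, 24),
                              noise_sd = 1, seed = 6)
  fit <- calibrate_rate(reps, ser)
  expect_length(fit$r_per_catalog, 3)
  expect_gt(fit$r_sd, 0)
  expect_equal(fit$r, mean(fit$r_per_catalog))
  g <- glance(fit)
  expect_equal(g$r, fit$r)
  expect_true(all(c("mean_abs_error_pct", "mean_rel_error_pct") %in% names(g)))
})

test_that("parameter recovery within 10% under 2-point observation noise", {
  # recovery accuracy is assessed on the mean fit over independent noisy
  # series (single noisy draws carry irreducible sampling error at low
  # rates, where the loss signal is a few percentage points)
  cat <- simulate_gene_catalog(3000, seed = 25)
  for (true_r in c(500, 5000)) {
    fits <- sapply(1:3, function(k) {
      ser <- simulate_loss_series(cat, rate = true_r,
                                  ages_weeks = c(8, 14, 20),
                                  noise_sd = 2, seed = true_r + k)
      calibrate_rate(cat, ser, calibrate_on = "last", t0_weeks = 0)$r
    })
    expect_lt(abs(mean(fits) - true_r) / true_r, 0.10)
  }
})

test_that("validation errors follow the error formulas", {
  # model 50%, data 40% -> absolute 10, relative 25
  cat <- simulate_gene_catalog(500, seed = 26)
  ser <- simulate_loss_series(cat, 1000, c(10, 20), noise_sd = 0, seed = 1)
  fit <- calibrate_rate(cat, ser)
  v <- validate_rate(fit)
  manual_pred <- 100 * expected_loss(
    cat, age_to_count(fit$r, ser$age_weeks * 7, 0))
  expect_equal(v$predicted_pct, manual_pred)
  expect_equal(v$abs_error_pct, abs(manual_pred - ser$loss_pct))
  expect_equal(v$rel_error_pct,
               abs(manual_pred - ser$loss_pct) / ser$loss_pct * 100)
})

test_that("repair-capacity arithmetic reproduces the genotype comparisons", {
  rc <- repair_capacity(1621, 4978)
  expect_equal(rc$daily_difference, 3357)
  expect_equal(rc$percent_of_reference, 67.4, tolerance = 0.05)
  wt <- repair_capacity(62, 4978)
  expect_equal(wt$percent_persisting, 1.2, tolerance = 0.05)
  expect_equal(wt$percent_repaired, 98.8, tolerance = 0.05)
  same <- repair_capacity(10, 10)
  expect_equal(same$daily_difference, 0)
  expect_equal(same$percent_of_reference, 0)
  expect_equal(repair_capacity(2315, 4978)$percent_of_reference, 53.5,
               tolerance = 0.05)
})

test_that("residual-activity projection scales and rounds", {
  expect_equal(project_residual_rate(4978, 0.075), 4605)
  expect_equal(project_residual_rate(4978, 1), 0)
  expect_equal(project_residual_rate(4978, 0), 4978)
  expect_error(project_residual_rate(100, 1.5), "residual_fraction")
})
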