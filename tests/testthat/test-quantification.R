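fv <- function(mode10 = 0, max30 = 0, avg20 = 0, min30 = 0, avg30 = NULL) {
  if (is.null(avg30)) avg30 <- avg20
  structure(list(mode10 = mode10, max30 = max30, min30 = min30,
                 avg20 = avg20, avg30 = avg30,
                 max_minus_avg20 = max30 - avg20,
                 max_minus_avg30 = max30 - avg30),
            class = "feature_vector")
}

test_that("the four zero rules fire in order", {
  expect_true(classify_zero(fv(max30 = 0)))
  expect_equal(zero_rule_fired(fv(max30 = 0)), 1L)
  expect_true(classify_zero(fv(mode10 = 0, max30 = 4)))
  expect_equal(zero_rule_fired(fv(mode10 = 0, max30 = 4)), 2L)
  # mode10/max30 = 0.5 < 0.8
  expect_true(classify_zero(fv(mode10 = 5, max30 = 10, avg20 = 2)))
  expect_equal(zero_rule_fired(fv(mode10 = 5, max30 = 10, avg20 = 2)), 3L)
  # ratio 1.0 but max30 - avg20 = 0.6 < 1
  expect_true(classify_zero(fv(mode10 = 4, max30 = 4, avg20 = 3.4)))
  expect_equal(zero_rule_fired(fv(mode10 = 4, max30 = 4, avg20 = 3.4)), 4L)
  # genuine response falls through all four rules
  expect_false(classify_zero(fv(mode10 = 38, max30 = 40, avg20 = 35)))
  expect_equal(zero_rule_fired(fv(mode10 = 38, max30 = 40, avg20 = 35)), 0L)
})

test_that("rule thresholds are strict inequalities", {
  # ratio exactly 0.8 falls through rule 3; diff 5 >= 1 passes rule 4
  expect_false(classify_zero(fv(mode10 = 8, max30 = 10, avg20 = 5)))
  # diff exactly 1 falls through rule 4
  expect_false(classify_zero(fv(mode10 = 10, max30 = 10, avg20 = 9)))
  # just below the thresholds still classifies zero
  expect_true(classify_zero(fv(mode10 = 8, max30 = 10 + 1e-9, avg20 = 5)))
  expect_true(classify_zero(fv(mode10 = 10, max30 = 10, avg20 = 9 + 1e-9)))
})

test_that("exactly one decision branch fires for any feature vector", {
  set.seed(19)
  for (i in 1:200) {
    f <- fv(mode10 = sample(0:20, 1), max30 = sample(0:20, 1),
            avg20 = runif(1, 0, 20))
    rule <- zero_rule_fired(f)
    expect_true(rule %in% 0:4)
    expect_identical(classify_zero(f), rule > 0L)
  }
})

test_that("calibration recovers exact lines", {
  m <- fit_calibration(data.frame(concentration = c(10, 20),
                                  mean_peak = c(10, 20)),
                       exclude_zero = FALSE)
  expect_equal(m$slope, 1)
  expect_equal(m$intercept, 0, tolerance = 1e-12)
  # concentration = 0.5 * peak - 2 at peaks {24, 104, 204}
  peaks <- c(24, 104, 204)
  m2 <- fit_calibration(data.frame(concentration = 0.5 * peaks - 2,
                                   mean_peak = peaks))
  expect_equal(m2$slope, 0.5)
  expect_equal(m2$intercept, -2)
  expect_equal(m2$fitted_peak_range, c(24, 204))
})

test_that("calibration equals the normal-equations oracle on noisy points", {
  set.seed(23)
  for (i in 1:20) {
    peaks <- sort(runif(10, 5, 600))
    conc <- 0.37 * peaks + rnorm(10, 0, 3)
    m <- fit_calibration(data.frame(concentration = conc, mean_peak = peaks),
                         exclude_zero = FALSE)
    o <- oracle_ols(peaks, conc)
    expect_equal(m$slope, o$slope, tolerance = 1e-9)
    expect_equal(m$intercept, o$intercept, tolerance = 1e-9)
  }
})

test_that("the zero point is excluded from the fit by default", {
  pts <- data.frame(concentration = c(0, 10, 20), mean_peak = c(5, 10, 20))
  m <- fit_calibration(pts)                       # zero row dropped
  expect_equal(m$created_from, 2)
  expect_equal(m$slope, 1)
  m_all <- fit_calibration(pts, exclude_zero = FALSE)
  expect_equal(m_all$created_from, 3)
  expect_false(isTRUE(all.equal(m$slope, m_all$slope)))
})

test_that("degenerate calibration inputs are rejected", {
  expect_error(fit_calibration(data.frame(concentration = 0, mean_peak = 1)),
               "at least 2")
  expect_error(
    fit_calibration(data.frame(concentration = c(10, 20),
                               mean_peak = c(7, 7)), exclude_zero = FALSE),
    "identical")
})

test_that("predictions follow the line and clamp to the sensor range", {
  m <- structure(list(slope = 0.5, intercept = -2,
                      fitted_peak_range = c(0, 600), exclude_zero = TRUE,
                      created_from = 9),
                 class = "brac_model")
  expect_equal(predict_concentration(m, 104), 50)
  expect_equal(predict_concentration(m, 2), 0)    # raw -1 clamps to 0
  m1 <- structure(list(slope = 1, intercept = 0,
                       fitted_peak_range = c(0, 600), exclude_zero = TRUE,
                       created_from = 9),
                  class = "brac_model")
  expect_equal(predict_concentration(m1, 350), 300)
  expect_error(predict_concentration(m1, -1), "non-negative")
  # with positive slope, predictions are non-decreasing in the peak
  expect_true(all(diff(predict_concentration(m, seq(0, 700, by = 10))) >= 0))
})

test_that("model JSON serialization round-trips exactly", {
  pts <- calibration_points(generate_dataset(c(0, 10, 50, 150), 3, seed = 2))
  m <- fit_calibration(pts)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  expect_identical(read_model(path), m)
})

test_that("quantify composes classifier and regression", {
  np <- sim_params(noise_amplitude = 0, zero_bump_amplitude = 0)
  model <- fit_calibration(calibration_points(generate_dataset(params = np,
                                                               seed = 1)))
  # all-zero trace -> zero-classified
  r0 <- quantify(sensor_trace(rep(0, 60)), model)
  expect_true(r0$is_zero_classified)
  expect_equal(r0$value, 0)
  expect_equal(r0$rule_fired, 1L)
  # noiseless 50 mcg/100 mL trace recovers its label
  r50 <- quantify(generate_trace(50, np, seed = 1), model)
  expect_false(r50$is_zero_classified)
  expect_equal(r50$value, 50, tolerance = 0.5 / 50)
  # default zero-concentration traces (with noise and pump bump) read zero
  noisy_model <- fit_calibration(calibration_points(generate_dataset(seed = 1)))
  for (s in 1:20) {
    r <- quantify(generate_trace(0, sim_params(), seed = s), noisy_model)
    expect_true(r$is_zero_classified)
    expect_equal(r$value, 0)
  }
})

test_that("noiseless round trip recovers labels within one quantization step", {
  np <- sim_params(noise_amplitude = 0, zero_bump_amplitude = 0)
  traces <- generate_dataset(trials_per_concentration = 2, params = np,
                             seed = 4)
  model <- fit_calibration(calibration_points(traces))
  preds <- quantify_dataset(traces, model)
  nonzero <- preds[preds$actual > 0, ]
  expect_true(all(abs(nonzero$predicted - nonzero$actual) <= model$slope))
  expect_true(all(preds$predicted[preds$actual == 0] == 0))
})
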