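test_that("error metrics match hand computation", {
  a <- c(10, 10, 10)
  p <- c(9, 10, 11)
  expect_equal(mse(a, p), 2 / 3)
  expect_equal(rmse(a, p), sqrt(2 / 3))
  expect_equal(mae(a, p), 2 / 3)
  expect_equal(mse(a, a), 0)
  expect_equal(rmse(a, a), 0)
  expect_equal(mae(a, a), 0)
  expect_equal(mae(4, 3.98), 0.02)
  expect_error(mse(numeric(0), numeric(0)), "at least one")
  expect_error(mae(1:3, 1:2), "equal length")
})

test_that("R-squared matches its definition", {
  a <- c(0, 10, 20)
  expect_equal(r_squared(a, a), 1)
  expect_equal(r_squared(a, rep(mean(a), 3)), 0)
  expect_equal(r_squared(a, c(0, 9, 21)), 1 - 2 / 200)
  expect_error(r_squared(c(5, 5), c(4, 6)), "constant")
})

test_that("accuracy percentage uses the absolute relative error", {
  expect_equal(accuracy_percent(10, 9.28), 92.8)
  expect_equal(accuracy_percent(25, 25 - 0.34), 98.64)
  expect_equal(accuracy_percent(50, 50), 100)
  # over-prediction cannot exceed 100%
  expect_equal(accuracy_percent(10, 10.72), 92.8)
  # zero actual: only an exact zero prediction is accurate
  expect_equal(accuracy_percent(0, 0), 100)
  expect_equal(accuracy_percent(0, 0.5), 0)
  expect_error(accuracy_percent(-1, 0), ">= 0")
})

test_that("RSD is the SD as a percentage of the mean", {
  expect_equal(rsd(c(9, 10, 11)), 10)
  expect_equal(rsd(rep(7, 5)), 0)
  expect_equal(rsd(rep(0, 5)), 0)
  expect_error(rsd(5), "at least 2")
  expect_error(rsd(c(-1, 1)), "undefined")
})

test_that("group evaluation mirrors a validation-table row", {
  g <- evaluate_group(10, c(9, 10, 11))
  expect_equal(g$mean_predicted, 10)
  expect_equal(g$avg_accuracy, 100 - 100 * (2 / 3) / 10)
  expect_equal(g$mae, 2 / 3)
  expect_equal(g$rmse, sqrt(g$mse))
  expect_equal(g$sd, 1)
  expect_equal(g$rsd, 10)
  # all-zero group: perfect accuracy, no deviation
  g0 <- evaluate_group(0, rep(0, 4))
  expect_equal(g0$avg_accuracy, 100)
  expect_equal(g0$mse + g0$mae + g0$rmse + g0$sd + g0$rsd, 0)
  # constant perfect predictions
  g50 <- evaluate_group(50, rep(50, 3))
  expect_equal(g50$avg_accuracy, 100)
  expect_equal(g50$rsd, 0)
  # single prediction: sample SD undefined
  g1 <- evaluate_group(20, 19)
  expect_true(is.na(g1$sd) && is.na(g1$rsd))
})

test_that("overall aggregation is the unweighted mean across groups", {
  groups <- do.call(rbind, list(evaluate_group(10, c(9, 10, 11)),
                                evaluate_group(50, c(48, 52))))
  rep_ <- evaluate_overall(groups,
                           actual = c(10, 10, 10, 50, 50),
                           predicted = c(9, 10, 11, 48, 52))
  expect_equal(rep_$overall_accuracy, mean(groups$avg_accuracy))
  expect_equal(rep_$overall_mse, mean(groups$mse))
  expect_equal(rep_$overall_mae, mean(groups$mae))
  expect_equal(rep_$overall_rmse, sqrt(rep_$overall_mse))
  single <- evaluate_overall(groups[1, ])
  expect_equal(single$overall_accuracy, groups$avg_accuracy[1])
  expect_equal(single$overall_mse, groups$mse[1])
  expect_true(is.na(single$overall_r2))
})

test_that("metric identities and oracle agreement hold on random pair sets", {
  set.seed(29)
  for (i in 1:100) {
    n <- sample(2:30, 1)
    a <- runif(n, 1, 200)
    p <- a + rnorm(n, 0, 5)
    p <- pmax(p, 0)
    # brute-force recomputation
    expect_equal(mse(a, p), sum((p - a)^2) / n)
    expect_equal(mae(a, p), sum(abs(p - a)) / n)
    expect_equal(rmse(a, p), sqrt(mse(a, p)))
    expect_true(mae(a, p) <= rmse(a, p) + 1e-12)
    # group accuracy identity at constant actual
    g <- evaluate_group(a[1], p)
    expect_equal(g$avg_accuracy, 100 - 100 * mae(rep(a[1], n), p) / a[1])
  }
})

test_that("r_squared is 1 exactly when predictions equal actuals", {
  set.seed(31)
  a <- runif(10, 0, 100)
  expect_equal(r_squared(a, a), 1)
  expect_lt(r_squared(a, a + c(rep(0, 9), 0.5)), 1)
})

test_that("the formatted report rounds half up at presentation only", {
  g <- evaluate_group(10, c(10.125, 10.125))
  tab <- format_report(evaluate_overall(g))
  expect_equal(tab$AveragePredicted[1], 10.13)  # round() alone gives 10.12
  expect_equal(g$mean_predicted, 10.125)        # internal value untouched
})

test_that("report CSV carries the table and provenance header", {
  res <- evaluate_predictions(c(0, 0, 10, 10), c(0, 0, 9, 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(res, path, header = c(seed = "1"))
  lines <- readLines(path)
  expect_match(lines[1], "^# seed: 1")
  tab <- utils::read.csv(path, comment.char = "#")
  expect_equal(nrow(tab), 3)  # two groups + overall
  expect_equal(names(tab)[1:3],
               c("ActualConcentration", "AveragePredicted", "AverageAccuracy"))
})

test_that("train/validation split partitions the data reproducibly", {
  traces <- as.list(1:200)
  s <- split_dataset(traces, 0.9, seed = 7)
  expect_length(s$train, 180)
  expect_length(s$validation, 20)
  expect_setequal(c(unlist(s$train), unlist(s$validation)), 1:200)
  expect_length(intersect(unlist(s$train), unlist(s$validation)), 0)
  s2 <- split_dataset(traces, 0.9, seed = 7)
  expect_identical(s, s2)
  half <- split_dataset(as.list(1:2), 0.5, seed = 1)
  expect_length(half$train, 1)
  expect_length(half$validation, 1)
  # half counts round up on the training side
  odd <- split_dataset(as.list(1:5), 0.5, seed = 1)
  expect_length(odd$train, 3)
  expect_error(split_dataset(traces, 0), "between 0 and 1")
  expect_error(split_dataset(traces, 1), "between 0 and 1")
})
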