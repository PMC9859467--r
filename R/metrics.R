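#' Error metrics for predicted vs. actual BrAC
#'
#' Standard analytical validation metrics over paired actual/predicted
#' concentrations: mean square error, root mean square error and mean
#' absolute error, all in (mcg/100 mL) units (squared for MSE).
#'
#' @param actual Actual concentrations (BrACa), mcg/100 mL.
#' @param predicted Predicted concentrations (BrACe), mcg/100 mL.
#' @return A scalar.
#' @export
#' @examples
#' mse(c(10, 10, 10), c(9, 10, 11))  # 2/3
#' rmse(c(10, 10, 10), c(9, 10, 11)) # sqrt(2/3)
mse <- function(actual, predicted) {
  check_pairs(actual, predicted)
  mean((predicted - actual)^2)
}

#' @rdname mse
#' @export
rmse <- function(actual, predicted) sqrt(mse(actual, predicted))

#' @rdname mse
#' @export
mae <- function(actual, predicted) {
  check_pairs(actual, predicted)
  mean(abs(predicted - actual))
}

check_pairs <- function(actual, predicted) {
  if (length(actual) == 0)
    stop("need at least one actual/predicted pair", call. = FALSE)
  if (length(actual) != length(predicted))
    stop("`actual` and `predicted` must have equal length", call. = FALSE)
  invisible(TRUE)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((actual - predicted)^2) / sum((actual - mean(actual))^2)`,
#' pooled over all pairs. Requires at least two pairs with non-constant
#' actual values.
#'
#' @inheritParams mse
#' @return A scalar (1 for perfect prediction).
#' @export
r_squared <- function(actual, predicted) {
  check_pairs(actual, predicted)
  if (length(actual) < 2 || length(unique(actual)) < 2)
    stop("R^2 is undefined for constant actual values", call. = FALSE)
  ss_res <- sum((actual - predicted)^2)
  ss_tot <- sum((actual - mean(actual))^2)
  1 - ss_res / ss_tot
}

#' Per-measurement accuracy percentage
#'
#' `100 - 100 * |actual - predicted| / actual` for positive actual
#' concentrations. For an actual concentration of zero the ratio is
#' undefined; a prediction of exactly zero counts as 100% accurate and any
#' other prediction as 0% (a false positive). The absolute error is used so
#' over-predictions cannot score above 100%; averaged over a group of
#' trials this makes the group accuracy identically
#' `100 - 100 * MAE / actual`.
#'
#' @inheritParams mse
#' @return Accuracy percentage(s), vectorized over pairs.
#' @export
accuracy_percent <- function(actual, predicted) {
  check_pairs(actual, predicted)
  if (any(actual < 0)) stop("actual concentrations must be >= 0", call. = FALSE)
  ifelse(actual > 0,
         100 - 100 * abs(actual - predicted) / actual,
         ifelse(predicted == 0, 100, 0))
}

#' Relative standard deviation
#'
#' `100 * sd(values) / mean(values)`, the precision measure used to judge
#' repeatability across trials of one concentration. When the sample
#' standard deviation is zero the RSD is zero regardless of the mean
#' (covers the all-zero-prediction group); otherwise a positive mean is
#' required.
#'
#' @param values Predicted concentrations for one group (>= 2 values).
#' @return RSD in percent.
#' @export
#' @examples
#' rsd(c(9, 10, 11)) # sd 1, mean 10 -> 10%
rsd <- function(values) {
  if (length(values) < 2)
    stop("RSD needs at least 2 values (sample SD undefined)", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) return(0)
  m <- mean(values)
  if (m <= 0)
    stop("RSD is undefined for non-positive mean with non-zero SD",
         call. = FALSE)
  100 * s / m
}

#' Evaluate predictions for one concentration group
#'
#' Computes the per-concentration row of a validation report: mean
#' prediction, trial-averaged accuracy, MSE, MAE, RMSE, sample SD of the
#' predictions and RSD. With a single prediction the sample SD (and hence
#' RSD) is undefined and reported as `NA`.
#'
#' @param actual The group's actual concentration, mcg/100 mL.
#' @param predictions Predicted concentrations for that group's trials.
#' @return A one-row data frame (class `group_evaluation`).
#' @export
evaluate_group <- function(actual, predictions) {
  if (length(predictions) == 0)
    stop("need at least one prediction", call. = FALSE)
  a <- rep(actual, length(predictions))
  s <- if (length(predictions) >= 2) stats::sd(predictions) else NA_real_
  out <- data.frame(
    actual_concentration = actual,
    mean_predicted = mean(predictions),
    avg_accuracy = mean(accuracy_percent(a, predictions)),
    mse = mse(a, predictions),
    mae = mae(a, predictions),
    rmse = rmse(a, predictions),
    sd = s,
    rsd = if (is.na(s)) NA_real_
          else if (s == 0) 0
          else rsd(predictions)
  )
  class(out) <- c("group_evaluation", "data.frame")
  out
}

#' Aggregate group evaluations into an overall report
#'
#' The overall row aggregates unweighted across groups: overall accuracy is
#' the mean of the group accuracies, overall MSE the mean of the group MSEs
#' (with overall RMSE its square root), and overall MAE the mean of the
#' group MAEs. R-squared is computed from the pooled actual/predicted pairs,
#' not per group.
#'
#' @param groups A data frame of group rows ([evaluate_group()] results,
#'   row-bound).
#' @param actual,predicted Optional pooled pairs for the overall R^2;
#'   omitted, `overall_r2` is `NA`.
#' @return An object of class `evaluation_report`: list with `groups` and
#'   the overall metrics.
#' @export
evaluate_overall <- function(groups, actual = NULL, predicted = NULL) {
  stopifnot(is.data.frame(groups), nrow(groups) >= 1)
  overall_mse <- mean(groups$mse)
  structure(
    list(groups = groups,
         overall_accuracy = mean(groups$avg_accuracy),
         overall_mse = overall_mse,
         overall_mae = mean(groups$mae),
         overall_rmse = sqrt(overall_mse),
         overall_r2 = if (is.null(actual)) NA_real_
                      else r_squared(actual, predicted)),
    class = "evaluation_report"
  )
}

#' Full evaluation of paired predictions
#'
#' Groups pairs by actual concentration, evaluates each group and
#' aggregates, mirroring the structure of a device validation table.
#'
#' @inheritParams mse
#' @return An `evaluation_report`.
#' @export
evaluate_predictions <- function(actual, predicted) {
  check_pairs(actual, predicted)
  groups <- do.call(rbind, lapply(sort(unique(actual)), function(a) {
    evaluate_group(a, predicted[actual == a])
  }))
  r2_pairs <- length(unique(actual)) >= 2
  evaluate_overall(groups,
                   actual = if (r2_pairs) actual,
                   predicted = if (r2_pairs) predicted)
}

#' @export
print.evaluation_report <- function(x, digits = 2, ...) {
  cat("Per-concentration evaluation (mcg/100 mL):\n")
  print(format_report(x, digits), row.names = FALSE)
  invisible(x)
}

#' Format an evaluation report as a presentation table
#'
#' Rounds to `digits` decimals (half away from zero) at presentation only;
#' all internal computation is full precision. Columns follow the standard
#' validation-table layout, with an `Overall` row appended.
#'
#' @param report An `evaluation_report`.
#' @param digits Decimals for presentation rounding.
#' @return A data frame.
#' @export
format_report <- function(report, digits = 2) {
  g <- report$groups
  rnd <- function(x) round_half_up(x, digits)
  rows <- data.frame(
    ActualConcentration = g$actual_concentration,
    AveragePredicted = rnd(g$mean_predicted),
    AverageAccuracy = rnd(g$avg_accuracy),
    MSE = rnd(g$mse), MAE = rnd(g$mae), RMSE = rnd(g$rmse),
    R2 = NA_real_,
    StandardDeviation = rnd(g$sd), RSD = rnd(g$rsd),
    stringsAsFactors = FALSE
  )
  overall <- data.frame(
    ActualConcentration = NA_real_,
    AveragePredicted = NA_real_,
    AverageAccuracy = rnd(report$overall_accuracy),
    MSE = rnd(report$overall_mse), MAE = rnd(report$overall_mae),
    RMSE = rnd(report$overall_rmse),
    R2 = round_half_up(report$overall_r2, 4),
    StandardDeviation = NA_real_, RSD = NA_real_
  )
  rbind(rows, overall)
}

# round() rounds half to even; tables are presented half away from zero.
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Write an evaluation report to CSV
#'
#' @param report An `evaluation_report`.
#' @param path File path.
#' @param header Optional named character vector written as `# key: value`
#'   comment lines before the table (e.g. seed and package version).
#' @export
write_report <- function(report, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(paste0("# ", names(header), ": ", header), con)
  utils::write.csv(format_report(report), con, row.names = FALSE)
  invisible(path)
}

#' Random train/validation split of a trace collection
#'
#' Seeded random partition into a training set of `round(n * fraction)`
#' traces (half counts round up) and a validation set of the rest; the two
#' are disjoint and together contain every input trace.
#'
#' @param traces A list of traces (or any list).
#' @param train_fraction Fraction in (0, 1) assigned to training
#'   (default 0.9).
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return A list with elements `train` and `validation`.
#' @export
#' @examples
#' s <- split_dataset(as.list(1:200), 0.9, seed = 7)
#' lengths(s) # 180 train, 20 validation
split_dataset <- function(traces, train_fraction = 0.9, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be strictly between 0 and 1", call. = FALSE)
  n <- length(traces)
  n_train <- floor(n * train_fraction + 0.5)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = traces[sort(idx)],
       validation = traces[setdiff(seq_len(n), idx)])
}
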