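#' Threshold parameters for the zero-concentration classifier
#'
#' @param ratio_threshold Minimum `mode10 / max30` ratio a genuine sample
#'   must reach: readings fluctuate near the peak during the first 10
#'   samples, so the mode should sit close to the maximum. Below this ratio
#'   the trace is classified as alcohol-free.
#' @param diff_threshold Minimum distance in counts between `max30` and
#'   `avg20` for a genuine sample: a real response peaks and then trends
#'   down, while a bare noise plateau does not separate from its own average.
#' @return An object of class `threshold_params`.
#' @export
threshold_params <- function(ratio_threshold = 0.8, diff_threshold = 1) {
  stopifnot(ratio_threshold > 0, ratio_threshold < 1, diff_threshold > 0)
  structure(list(ratio_threshold = ratio_threshold,
                 diff_threshold = diff_threshold),
            class = "threshold_params")
}

#' Four-rule zero-concentration classifier
#'
#' Applies the four rules in fixed order, returning `TRUE` (alcohol-free)
#' on the first that fires:
#' \enumerate{
#'   \item `max30 == 0` — no change in the digital signal at all;
#'   \item `mode10 == 0` — no reaction sufficient to shift the most frequent
#'     early reading off baseline;
#'   \item `mode10 / max30 < ratio_threshold` (default 0.8) — an isolated
#'     spike unsupported by a plateau of readings near the peak;
#'   \item `max30 - avg20 < diff_threshold` (default 1 count) — an
#'     insufficient peak that never separates from the early average,
#'     i.e. electrical noise.
#' }
#' Otherwise the trace is taken to contain alcohol and is passed to the
#' linear calibration. Rules 3 and 4 use strict inequalities; equality falls
#' through to the next rule.
#'
#' @param features A [extract_features()] result.
#' @param params A [threshold_params()] object.
#' @return Logical flag: `TRUE` if classified as zero concentration.
#' @export
classify_zero <- function(features, params = threshold_params()) {
  stopifnot(inherits(params, "threshold_params"))
  if (features$max30 == 0) return(TRUE)
  if (features$mode10 == 0) return(TRUE)
  if (features$mode10 / features$max30 < params$ratio_threshold) return(TRUE)
  if (features$max30 - features$avg20 < params$diff_threshold) return(TRUE)
  FALSE
}

#' Which threshold rule fires for a feature vector
#'
#' Diagnostic companion to [classify_zero()]: returns 1--4 for the rule that
#' classified the trace as zero, or 0 if no rule fired (the trace proceeds
#' to quantification).
#'
#' @inheritParams classify_zero
#' @return Integer in 0..4.
#' @export
zero_rule_fired <- function(features, params = threshold_params()) {
  if (features$max30 == 0) return(1L)
  if (features$mode10 == 0) return(2L)
  if (features$mode10 / features$max30 < params$ratio_threshold) return(3L)
  if (features$max30 - features$avg20 < params$diff_threshold) return(4L)
  0L
}

#' Peak-averaged calibration points from labeled traces
#'
#' For each distinct concentration in the dataset, averages the `max30`
#' (peak) feature over that concentration's trials. Averaging over trials,
#' rather than calibrating against a single point, avoids biasing the line
#' toward any one calibration point.
#'
#' @param traces A list of labeled [sensor_trace()] objects.
#' @return A data frame with columns `concentration` and `mean_peak`,
#'   ordered by concentration.
#' @export
calibration_points <- function(traces) {
  feats <- extract_features_dataset(traces)
  if (any(is.na(feats$true_concentration)))
    stop("all traces must carry a true_concentration label", call. = FALSE)
  agg <- stats::aggregate(max30 ~ true_concentration, data = feats, FUN = mean)
  out <- data.frame(concentration = agg$true_concentration,
                    mean_peak = agg$max30)
  out[order(out$concentration), , drop = FALSE]
}

#' Fit the linear calibration of concentration on averaged peak
#'
#' Ordinary least-squares fit of concentration (y) on the per-concentration
#' averaged peak counts (x). The zero-concentration point is excluded by
#' default: alcohol-free samples are handled by the threshold classifier,
#' and keeping the zero point in the regression would distort the line in
#' the region the classifier never reaches.
#'
#' @param points A data frame of calibration points (`concentration`,
#'   `mean_peak`), e.g. from [calibration_points()].
#' @param exclude_zero Drop the concentration-0 point before fitting
#'   (default `TRUE`).
#' @return An object of class `brac_model` with `slope` (mcg/100 mL per
#'   count), `intercept` (mcg/100 mL) and `fitted_peak_range`.
#' @export
#' @examples
#' pts <- data.frame(concentration = c(10, 20), mean_peak = c(10, 20))
#' fit_calibration(pts, exclude_zero = FALSE) # slope 1, intercept 0
fit_calibration <- function(points, exclude_zero = TRUE) {
  stopifnot(is.data.frame(points),
            all(c("concentration", "mean_peak") %in% names(points)))
  if (exclude_zero) points <- points[points$concentration != 0, , drop = FALSE]
  if (nrow(points) < 2)
    stop("need at least 2 calibration points after exclusion", call. = FALSE)
  if (length(unique(points$mean_peak)) < 2)
    stop("calibration peaks are all identical; cannot fit a line",
         call. = FALSE)
  fit <- stats::lm(concentration ~ mean_peak, data = points)
  structure(
    list(slope = unname(stats::coef(fit)["mean_peak"]),
         intercept = unname(stats::coef(fit)["(Intercept)"]),
         fitted_peak_range = range(points$mean_peak),
         exclude_zero = exclude_zero,
         created_from = nrow(points)),
    class = "brac_model"
  )
}

#' @export
print.brac_model <- function(x, ...) {
  cat(sprintf(
    "<brac_model> BrAC = %.6g * max30 %+.6g  (fitted on %d points, peaks %g-%g)\n",
    x$slope, x$intercept, x$created_from,
    x$fitted_peak_range[1], x$fitted_peak_range[2]))
  invisible(x)
}

#' Predict a concentration from a peak count
#'
#' Applies the calibration line `slope * max30 + intercept` and clamps the
#' result to the physical sensor range `[0, 300]` mcg/100 mL: concentrations
#' cannot be negative and the sensor cannot resolve beyond its ceiling.
#'
#' @param model A [fit_calibration()] model.
#' @param max30 Peak count(s), non-negative.
#' @param sensor_max Upper clamp in mcg/100 mL.
#' @return Concentration(s) in mcg/100 mL.
#' @export
predict_concentration <- function(model, max30, sensor_max = 300) {
  stopifnot(inherits(model, "brac_model"))
  if (any(max30 < 0)) stop("`max30` must be non-negative", call. = FALSE)
  pmin(pmax(model$slope * max30 + model$intercept, 0), sensor_max)
}

#' Quantify the BrAC of a sensor trace
#'
#' The full per-trace pipeline: extract features, run the four-rule zero
#' classifier, and — only if the trace is not classified as alcohol-free —
#' apply the linear calibration to the peak.
#'
#' @param trace A [sensor_trace()].
#' @param model A [fit_calibration()] model.
#' @param params A [threshold_params()] object.
#' @return An object of class `brac_reading`: list with `value`
#'   (mcg/100 mL), `is_zero_classified`, and `rule_fired` (0 when
#'   quantified by the regression).
#' @export
quantify <- function(trace, model, params = threshold_params()) {
  fv <- extract_features(trace)
  rule <- zero_rule_fired(fv, params)
  value <- if (rule > 0L) 0 else predict_concentration(model, fv$max30)
  structure(list(value = value,
                 is_zero_classified = rule > 0L,
                 rule_fired = rule),
            class = "brac_reading")
}

#' @export
print.brac_reading <- function(x, ...) {
  cat(sprintf("<brac_reading> %.2f mcg/100 mL%s\n", x$value,
              if (x$is_zero_classified)
                sprintf(" (zero-classified, rule %d)", x$rule_fired) else ""))
  invisible(x)
}

#' Quantify a collection of traces
#'
#' @param traces A list of [sensor_trace()] objects.
#' @inheritParams quantify
#' @return A data frame with `trial_id`, `actual` (the label, possibly NA),
#'   `predicted`, `is_zero_classified` and `rule_fired`.
#' @export
quantify_dataset <- function(traces, model, params = threshold_params()) {
  do.call(rbind, lapply(traces, function(tr) {
    r <- quantify(tr, model, params)
    data.frame(trial_id = tr$trial_id,
               actual = tr$true_concentration,
               predicted = r$value,
               is_zero_classified = r$is_zero_classified,
               rule_fired = r$rule_fired)
  }))
}

#' Save / load a calibration model as JSON
#'
#' Exact round-trip serialization of a [fit_calibration()] model.
#'
#' @param model A `brac_model`.
#' @param path File path.
#' @return `read_model()` returns the `brac_model`; `write_model()` returns
#'   `path` invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "brac_model"))
  # digits = I(17): doubles survive the decimal round-trip bit-exactly
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(slope = x$slope, intercept = x$intercept,
                 fitted_peak_range = as.numeric(x$fitted_peak_range),
                 exclude_zero = isTRUE(x$exclude_zero),
                 created_from = x$created_from),
            class = "brac_model")
}
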