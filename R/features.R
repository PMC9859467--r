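#' Extract the seven quantification features from a trace
#'
#' The first 30 readings (0--1500 ms, the area of interest) carry the
#' information used for quantification: the signal peaks there and begins its
#' downtrend toward baseline. Seven features are computed:
#' \describe{
#'   \item{mode10}{mode of readings 1--10 — the most repeated count while the
#'     signal fluctuates near the peak; when several counts are equally
#'     frequent the largest is taken}
#'   \item{max30}{maximum of readings 1--30 — the peak response}
#'   \item{min30}{minimum of readings 1--30 — the end point of the area of
#'     interest}
#'   \item{avg20}{mean of readings 1--20}
#'   \item{avg30}{mean of readings 1--30}
#'   \item{max_minus_avg20}{`max30 - avg20`}
#'   \item{max_minus_avg30}{`max30 - avg30`}
#' }
#' Averages are exact; no rounding is applied.
#'
#' @param trace A [sensor_trace()] (or any object with at least 30 integer
#'   readings in `$readings`).
#' @return An object of class `feature_vector` (a named list of the seven
#'   features).
#' @export
#' @examples
#' tr <- generate_trace(40, sim_params(noise_amplitude = 0), seed = 1)
#' extract_features(tr)
extract_features <- function(trace) {
  readings <- trace$readings
  if (length(readings) < 30)
    stop("feature extraction needs at least 30 readings, got ",
         length(readings), call. = FALSE)
  w30 <- readings[1:30]
  max30 <- max(w30)
  avg20 <- mean(readings[1:20])
  avg30 <- mean(w30)
  structure(
    list(mode10 = mode_largest(readings[1:10]),
         max30 = max30,
         min30 = min(w30),
         avg20 = avg20,
         avg30 = avg30,
         max_minus_avg20 = max30 - avg20,
         max_minus_avg30 = max30 - avg30),
    class = "feature_vector"
  )
}

# Mode of an integer vector; ties broken toward the largest modal value
# (conservative against falsely classifying a genuine peak plateau as zero).
mode_largest <- function(x) {
  counts <- table(x)
  modal <- as.numeric(names(counts)[counts == max(counts)])
  max(modal)
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector>\n")
  for (nm in names(x))
    cat(sprintf("  %-16s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Feature table for a collection of traces
#'
#' @param traces A list of [sensor_trace()] objects.
#' @return A data frame with `trial_id`, `true_concentration` and the seven
#'   features, one row per trace.
#' @export
extract_features_dataset <- function(traces) {
  do.call(rbind, lapply(traces, function(tr) {
    fv <- extract_features(tr)
    cbind(data.frame(trial_id = tr$trial_id,
                     true_concentration = tr$true_concentration),
          as.data.frame(unclass(fv)))
  }))
}

#' Write a feature table to CSV
#'
#' @param traces A list of [sensor_trace()] objects.
#' @param path File path.
#' @export
write_features <- function(traces, path) {
  utils::write.csv(extract_features_dataset(traces), path, row.names = FALSE)
  invisible(path)
}
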