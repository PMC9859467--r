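#' Simulation parameters for synthetic fuel-cell sensor traces
#'
#' Describes the digitized response of the fuel-cell sensor to a breath
#' sample of known ethanol concentration, as captured by the acquisition
#' board. The response amplitude is set by the sensor sensitivity mapped
#' through the ADC quantization step; its shape is a fast saturating rise to
#' the peak followed by a slow exponential decay toward baseline, with the
#' time-to-peak increasing with concentration (higher concentrations need
#' more time to reach the peak).
#'
#' @param sensitivity Sensor sensitivity, mV per mcg/100 mL.
#' @param adc_vref ADC reference voltage, volts.
#' @param adc_levels ADC quantization levels.
#' @param baseline Baseline signal in counts (the sensor is read only after
#'   its output has returned to baseline, so 0 by default).
#' @param n_readings Trace length in samples; 60 samples at 50 ms cover 3 s,
#'   twice the 30-reading area of interest.
#' @param tp_base_ms,tp_slope_ms Time-to-peak model: the response peaks at
#'   `tp_base_ms + tp_slope_ms * concentration` milliseconds (snapped to the
#'   50 ms sampling grid). Defaults place peaks between ~200 ms at trace
#'   concentrations near zero and ~1.4 s at the sensor ceiling.
#' @param rise_tau_ms Time constant of the saturating rise, ms. Small values
#'   give the near-immediate initial response (within 200 ms) characteristic
#'   of the fuel cell, with the signal plateauing near the peak.
#' @param decay_rate Exponential decay rate after the peak, per ms.
#' @param noise_amplitude Electrical noise amplitude in counts; each reading
#'   gets an integer perturbation uniform on `-noise_amplitude ..
#'   noise_amplitude`.
#' @param zero_bump_amplitude Amplitude in counts of the short above-baseline
#'   transient seen on alcohol-free samples (attributable to electrical noise
#'   and the actuation of the sampling pump).
#'
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(sensitivity = 13,
                       adc_vref = 4.94,
                       adc_levels = 1024L,
                       baseline = 0L,
                       n_readings = 60L,
                       tp_base_ms = 200,
                       tp_slope_ms = 4,
                       rise_tau_ms = 60,
                       decay_rate = 3e-4,
                       noise_amplitude = 1L,
                       zero_bump_amplitude = 2) {
  stopifnot(sensitivity > 0, adc_vref > 0, adc_levels > 1,
            baseline >= 0, n_readings >= 30,
            tp_base_ms > 0, tp_slope_ms >= 0, rise_tau_ms > 0,
            decay_rate >= 0, noise_amplitude >= 0, zero_bump_amplitude >= 0)
  p <- structure(
    list(sensitivity = sensitivity, adc_vref = adc_vref,
         adc_levels = as.integer(adc_levels), baseline = as.integer(baseline),
         n_readings = as.integer(n_readings),
         tp_base_ms = tp_base_ms, tp_slope_ms = tp_slope_ms,
         rise_tau_ms = rise_tau_ms, decay_rate = decay_rate,
         noise_amplitude = as.integer(noise_amplitude),
         zero_bump_amplitude = zero_bump_amplitude),
    class = "sim_params"
  )
  step <- 1000 * p$adc_vref / p$adc_levels
  peak_at_max <- p$baseline + p$sensitivity * 300 / step
  if (peak_at_max > p$adc_levels - 1L)
    stop("peak implied by the 300 mcg/100 mL sensor ceiling exceeds the ADC range",
         call. = FALSE)
  p
}

#' Construct a sensor trace
#'
#' A digitized fuel-cell response: a sequence of integer ADC counts sampled
#' every 50 ms, optionally labeled with the true concentration of the sample.
#'
#' @param readings Integer counts in `0 .. 1023`, at least 30 of them (the
#'   0--1500 ms area of interest).
#' @param true_concentration Optional label, mcg/100 mL.
#' @param trial_id Identifier string.
#' @param sampling_interval_ms Sampling interval; fixed at 50 ms.
#' @return An object of class `sensor_trace`.
#' @export
sensor_trace <- function(readings, true_concentration = NA_real_,
                         trial_id = "trace", sampling_interval_ms = 50) {
  if (sampling_interval_ms != 50)
    stop("sampling interval is fixed at 50 ms", call. = FALSE)
  if (length(readings) < 30)
    stop("a trace needs at least 30 readings (0-1500 ms area of interest)",
         call. = FALSE)
  if (any(readings != round(readings)) || any(readings < 0) ||
      any(readings > 1023))
    stop("readings must be integers in [0, 1023]", call. = FALSE)
  structure(
    list(readings = as.integer(readings),
         sampling_interval_ms = 50,
         true_concentration = true_concentration,
         trial_id = trial_id),
    class = "sensor_trace"
  )
}

#' @export
print.sensor_trace <- function(x, ...) {
  cat("<sensor_trace> ", x$trial_id, ": ", length(x$readings),
      " readings @ 50 ms, label = ",
      if (is.na(x$true_concentration)) "none"
      else paste0(x$true_concentration, " mcg/100 mL"),
      ", max = ", max(x$readings), " counts\n", sep = "")
  invisible(x)
}

# Run code with a private RNG stream so generation is reproducible without
# disturbing the caller's random state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Time-to-peak of the modeled response
#'
#' The modeled response peaks at `tp_base_ms + tp_slope_ms * concentration`
#' milliseconds, snapped to the 50 ms sampling grid — later peaks at higher
#' concentrations.
#'
#' @param concentration Concentration in mcg/100 mL.
#' @param params A [sim_params()] object.
#' @return Peak time in ms.
#' @export
time_to_peak_ms <- function(concentration, params = sim_params()) {
  tp <- params$tp_base_ms + params$tp_slope_ms * concentration
  pmax(50, round(tp / 50) * 50)
}

# Noiseless continuous response at times t (ms) for one concentration.
response_curve <- function(concentration, params, t) {
  step <- 1000 * params$adc_vref / params$adc_levels
  amplitude <- params$sensitivity * concentration / step
  if (amplitude == 0) return(rep(0, length(t)))
  tp <- time_to_peak_ms(concentration, params)
  tau <- params$rise_tau_ms
  rise_norm <- 1 - exp(-tp / tau)
  ifelse(t <= tp,
         amplitude * (1 - exp(-t / tau)) / rise_norm,
         amplitude * exp(-params$decay_rate * (t - tp)))
}

#' Generate a synthetic sensor trace
#'
#' Simulates the digital output of the fuel-cell sensor for a sample of the
#' given concentration. The noiseless response rises from baseline to a peak
#' of `round(sensitivity * concentration / adc_step)` counts above baseline
#' (reached later at higher concentrations) and then decays toward baseline.
#' Alcohol-free samples show only a small above-baseline transient plus
#' noise — the slight increase real clean samples produce — which the
#' zero-threshold classifier is designed to reject.
#'
#' @param concentration True concentration in mcg/100 mL, within the
#'   sensor range `[0, 300]`.
#' @param params A [sim_params()] object.
#' @param seed Integer seed; identical arguments and seed give an identical
#'   trace.
#' @param trial_id Identifier stored on the trace.
#' @return A [sensor_trace()].
#' @export
#' @examples
#' tr <- generate_trace(50, sim_params(noise_amplitude = 0), seed = 1)
#' max(tr$readings) # 135 counts: round(13 * 50 / 4.8242)
generate_trace <- function(concentration, params = sim_params(), seed = 1L,
                           trial_id = paste0("c", concentration)) {
  if (concentration < 0 || concentration > 300)
    stop("concentration out of sensor range [0, 300] mcg/100 mL",
         call. = FALSE)
  t <- (seq_len(params$n_readings) - 1) * 50
  signal <- response_curve(concentration, params, t)
  if (concentration == 0 && params$zero_bump_amplitude > 0) {
    # short pump-actuation transient centered at 100 ms
    signal <- signal + params$zero_bump_amplitude * exp(-(t - 100)^2 / 5000)
  }
  noise <- if (params$noise_amplitude > 0) {
    with_seed(seed,
      sample(-params$noise_amplitude:params$noise_amplitude,
             length(t), replace = TRUE))
  } else 0
  counts <- round(params$baseline + signal + noise)
  counts <- pmin(pmax(counts, 0), params$adc_levels - 1L)
  sensor_trace(counts, true_concentration = concentration,
               trial_id = trial_id)
}

#' Generate a calibration-style dataset of traces
#'
#' Reproduces the wet-bath calibration design by default: 10 concentrations
#' (0, 4, 10, 20, 30, 40, 50, 100, 150, 200 mcg/100 mL) with 20 trials each,
#' i.e. 200 labeled traces.
#'
#' @param concentrations Concentrations in mcg/100 mL.
#' @param trials_per_concentration Trials per concentration (>= 1).
#' @param params A [sim_params()] object.
#' @param seed Integer seed for the whole dataset.
#' @return A list of [sensor_trace()] objects, one per trial.
#' @export
generate_dataset <- function(concentrations = c(0, 4, 10, 20, 30, 40, 50,
                                                100, 150, 200),
                             trials_per_concentration = 20L,
                             params = sim_params(),
                             seed = 1L) {
  if (length(concentrations) == 0)
    stop("`concentrations` must not be empty", call. = FALSE)
  if (trials_per_concentration < 1)
    stop("`trials_per_concentration` must be >= 1", call. = FALSE)
  grid <- expand.grid(trial = seq_len(trials_per_concentration),
                      concentration = concentrations)
  lapply(seq_len(nrow(grid)), function(i) {
    conc <- grid$concentration[i]
    trial <- grid$trial[i]
    generate_trace(conc, params,
                   seed = (as.integer(seed) + 7919L * i) %% 2147483647L,
                   trial_id = sprintf("c%g_t%02d", conc, trial))
  })
}

#' Write / read traces as CSV
#'
#' One row per reading with columns `trial_id`, `true_concentration`,
#' `time_ms`, `count`; the writer and reader round-trip exactly.
#'
#' @param traces A list of [sensor_trace()] objects.
#' @param path File path.
#' @return `read_traces()` returns a list of [sensor_trace()] objects;
#'   `write_traces()` returns `path` invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "sensor_trace")) traces <- list(traces)
  rows <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(trial_id = tr$trial_id,
               true_concentration = tr$true_concentration,
               time_ms = (seq_along(tr$readings) - 1) * 50,
               count = tr$readings)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, colClasses = c(trial_id = "character"))
  lapply(split(df, factor(df$trial_id, levels = unique(df$trial_id))),
         function(d) {
           d <- d[order(d$time_ms), ]
           sensor_trace(d$count,
                        true_concentration = as.numeric(d$true_concentration[1]),
                        trial_id = d$trial_id[1])
         })
}
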