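#' Default configuration
#'
#' Bundles the tunable parameters of every stage: simulator, zero-threshold
#' classifier, device constants, and the evaluation design (train fraction
#' and seed). Defaults reproduce the device's stated settings: 13 mV per
#' mcg/100 mL sensitivity, 4.94 V / 1024-level ADC, 0.8 ratio and 1-count
#' difference thresholds, BBR 2300, 90/10 train/validation split.
#'
#' @return An object of class `brac_config`.
#' @export
default_config <- function() {
  structure(
    list(simulation = sim_params(),
         thresholds = threshold_params(),
         constants = device_constants(),
         evaluation = list(train_fraction = 0.9, seed = 1L)),
    class = "brac_config"
  )
}

#' Load / save a configuration as JSON
#'
#' The JSON mirrors the config sections by name; missing fields take the
#' documented defaults, and any invalid value is rejected with an error
#' naming the offending field. Save-then-load round-trips exactly.
#'
#' @param path File path.
#' @param config A `brac_config`.
#' @return `load_config()` returns a validated `brac_config`.
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_config(raw)
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "brac_config"))
  jsonlite::write_json(lapply(config, unclass), path,
                       auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

build_config <- function(raw) {
  section <- function(name, constructor) {
    given <- raw[[name]]
    if (is.null(given)) given <- list()
    known <- names(formals(constructor))
    bad <- setdiff(names(given), known)
    if (length(bad))
      stop("unknown ", name, " field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    tryCatch(do.call(constructor, given[intersect(names(given), known)]),
             error = function(e)
               stop("invalid ", name, " config: ", conditionMessage(e),
                    call. = FALSE))
  }
  ev <- if (is.null(raw$evaluation)) list() else raw$evaluation
  tf <- if (is.null(ev$train_fraction)) 0.9 else ev$train_fraction
  if (tf <= 0 || tf >= 1)
    stop("invalid evaluation config: train_fraction must be in (0, 1)",
         call. = FALSE)
  structure(
    list(simulation = section("simulation", sim_params),
         thresholds = section("thresholds", threshold_params),
         constants = section("constants", device_constants),
         evaluation = list(
           train_fraction = tf,
           seed = if (is.null(ev$seed)) 1L else as.integer(ev$seed))),
    class = "brac_config"
  )
}

# Small stable hash (FNV-1a over the serialized config) for provenance
# headers; not cryptographic.
config_hash <- function(config) {
  bytes <- utf8ToInt(jsonlite::toJSON(lapply(config, unclass),
                                      auto_unbox = TRUE, digits = NA))
  h <- 216613626
  for (b in bytes) h <- (bitwXor(as.integer(h), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full simulation-to-evaluation pipeline
#'
#' End-to-end study under one seed: simulate the calibration dataset,
#' split it 90/10 into training and validation, build peak-averaged
#' calibration points from the training traces, fit the linear model
#' (zero point excluded), quantify every validation trace through the
#' threshold classifier + regression, and evaluate per concentration group.
#'
#' @param config A `brac_config` (default [default_config()]).
#' @param seed Integer seed governing all randomness (simulation noise and
#'   the random split); defaults to the seed recorded in the config.
#' @param concentrations Concentrations simulated, mcg/100 mL.
#' @param trials_per_concentration Trials per concentration.
#' @param verbose Log stage-level progress; `verbose = 2` additionally logs
#'   which threshold rule fired for each zero-classified trace.
#' @return A list of class `brac_pipeline_result`: `report`
#'   (an `evaluation_report`), `model`, `predictions` (per-trace data
#'   frame), `seed` and `config_hash`.
#' @export
#' @examples
#' res <- run_pipeline(seed = 42)
#' res$report$overall_accuracy
run_pipeline <- function(config = default_config(),
                         seed = config$evaluation$seed,
                         concentrations = c(0, 4, 10, 20, 30, 40, 50,
                                            100, 150, 200),
                         trials_per_concentration = 20L,
                         verbose = FALSE) {
  stopifnot(inherits(config, "brac_config"))
  seed <- as.integer(seed)
  log_stage <- function(...) if (!isFALSE(verbose)) message("[pipeline] ", ...)

  log_stage("simulating ", length(concentrations), " x ",
            trials_per_concentration, " traces (seed ", seed, ")")
  traces <- generate_dataset(concentrations, trials_per_concentration,
                             config$simulation, seed)

  log_stage("splitting ", length(traces), " traces ",
            config$evaluation$train_fraction * 100, "/",
            (1 - config$evaluation$train_fraction) * 100)
  parts <- split_dataset(traces, config$evaluation$train_fraction,
                         seed = seed + 1L)

  log_stage("calibrating on ", length(parts$train), " training traces")
  model <- fit_calibration(calibration_points(parts$train),
                           exclude_zero = TRUE)

  log_stage("quantifying ", length(parts$validation), " validation traces")
  preds <- quantify_dataset(parts$validation, model, config$thresholds)
  if (identical(verbose, 2)) {
    zc <- preds[preds$is_zero_classified, ]
    for (i in seq_len(nrow(zc)))
      message("[pipeline]   ", zc$trial_id[i], " zero-classified by rule ",
              zc$rule_fired[i])
  }

  log_stage("evaluating per concentration group")
  report <- evaluate_predictions(preds$actual, preds$predicted)

  structure(list(report = report, model = model, predictions = preds,
                 seed = seed, config_hash = config_hash(config)),
            class = "brac_pipeline_result")
}

#' @export
print.brac_pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d, config %s)\n", x$seed, x$config_hash))
  print(x$model)
  print(x$report)
  invisible(x)
}
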