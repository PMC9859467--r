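#' Device constants for the fuel-cell breath analyzer
#'
#' Physical constants of the sensing chain: the ADC reference voltage and
#' resolution of the acquisition board, the sensor's voltage sensitivity to
#' breath alcohol, the sensor's detection ceiling, and the breath-to-blood
#' ratio (BBR) used to convert BrAC to BAC.
#'
#' @param adc_vref ADC reference voltage in volts. Inputs between 0 V and
#'   `adc_vref` map onto the integer count range.
#' @param adc_levels Number of ADC quantization levels (a power of two;
#'   counts span `0 .. adc_levels - 1`).
#' @param sensitivity Sensor sensitivity in mV per mcg/100 mL of BrAC.
#' @param sensor_max Maximum detectable concentration in mcg/100 mL.
#' @param bbr Breath-to-blood ratio (dimensionless; 2300 under Malaysian
#'   standards). Configurable because the ratio differs between
#'   jurisdictions.
#'
#' @return An object of class `device_constants` (a named list).
#' @export
#' @examples
#' dc <- device_constants()
#' adc_step_mv(dc) # 4.94 V over 1024 levels: ~4.82 mV per count
device_constants <- function(adc_vref = 4.94,
                             adc_levels = 1024L,
                             sensitivity = 13,
                             sensor_max = 300,
                             bbr = 2300) {
  stopifnot(adc_vref > 0, adc_levels > 0, sensitivity > 0,
            sensor_max > 0, bbr > 0)
  adc_levels <- as.integer(adc_levels)
  if (bitwAnd(adc_levels, adc_levels - 1L) != 0L)
    stop("`adc_levels` must be a power of two", call. = FALSE)
  structure(
    list(adc_vref = adc_vref, adc_levels = adc_levels,
         sensitivity = sensitivity, sensor_max = sensor_max, bbr = bbr),
    class = "device_constants"
  )
}

#' Voltage represented by one ADC count
#'
#' One quantization step of the analog-to-digital converter, in millivolts:
#' `1000 * adc_vref / adc_levels`. With the default 4.94 V reference and
#' 1024 levels each count is worth about 4.82 mV.
#'
#' @param constants A [device_constants()] object.
#' @return Step size in mV (scalar).
#' @export
adc_step_mv <- function(constants = device_constants()) {
  1000 * constants$adc_vref / constants$adc_levels
}

#' Convert a digital reading to millivolts
#'
#' @param count Integer ADC count(s) in `0 .. adc_levels - 1`.
#' @param constants A [device_constants()] object.
#' @return Voltage in mV.
#' @export
digital_to_voltage <- function(count, constants = device_constants()) {
  if (any(count < 0 | count > constants$adc_levels - 1L))
    stop("ADC count out of range [0, ", constants$adc_levels - 1L, "]",
         call. = FALSE)
  count * adc_step_mv(constants)
}

#' Convert between breath (BrAC) and blood (BAC) alcohol content
#'
#' BrAC in mcg/100 mL breath relates to BAC in mg/100 mL blood through the
#' breath-to-blood ratio: `bac = brac * bbr / 1000` (the factor 1000 converts
#' micrograms to milligrams). With the default BBR of 2300, 200 mcg/100 mL
#' BrAC corresponds to 460 mg/100 mL BAC.
#'
#' @param brac BrAC value(s) in mcg/100 mL, non-negative.
#' @param bac BAC value(s) in mg/100 mL, non-negative.
#' @param bbr Breath-to-blood ratio.
#' @return The converted concentration(s).
#' @export
brac_to_bac <- function(brac, bbr = 2300) {
  if (any(brac < 0)) stop("BrAC must be non-negative", call. = FALSE)
  stopifnot(bbr > 0)
  brac * bbr / 1000
}

#' @rdname brac_to_bac
#' @export
bac_to_brac <- function(bac, bbr = 2300) {
  if (any(bac < 0)) stop("BAC must be non-negative", call. = FALSE)
  stopifnot(bbr > 0)
  bac * 1000 / bbr
}
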