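# Gas and Faraday constants are fixed by definition, not user-tunable.
.R_GAS <- 8.314      # J / (K mol)
.FARADAY <- 96485    # C / mol

#' Nernst parameters for the fuel-cell open circuit potential
#'
#' The maximum open circuit potential (OCP) of the fuel cell follows the
#' Nernst relation from the standard reversible voltage, the temperature and
#' the ratio of reactant to product partial pressures at the electrodes.
#' Ethanol oxidation on platinum is dominated by the four-electron pathway
#' to acetic acid, hence `n = 4` by default.
#'
#' @param E0 Standard reversible voltage in volts.
#' @param T Temperature in kelvin.
#' @param n Number of electrons transferred in the reaction (integer >= 1).
#' @param Pr Partial pressure of the reactants (any positive unit, only the
#'   ratio `Pr / Pp` matters).
#' @param Pp Partial pressure of the products.
#'
#' @return An object of class `nernst_params`.
#' @export
nernst_params <- function(E0, T = 298.15, n = 4L, Pr = 1, Pp = 1) {
  if (T <= 0) stop("temperature must be positive", call. = FALSE)
  if (n < 1 || n != round(n)) stop("`n` must be a positive integer", call. = FALSE)
  if (Pr <= 0 || Pp <= 0)
    stop("partial pressures must be positive", call. = FALSE)
  structure(list(E0 = E0, T = T, n = as.integer(n), Pr = Pr, Pp = Pp),
            class = "nernst_params")
}

#' Open circuit potential from the Nernst equation
#'
#' Computes `E = E0 + (R * T) / (n * F) * log(Pr / Pp)` with
#' R = 8.314 J/(K mol) and F = 96485 C/mol. This is the thermodynamic
#' ceiling of the cell voltage; an operating fuel cell sits below it due to
#' ohmic, activation and mass-transport losses.
#'
#' @param params A [nernst_params()] object.
#' @return Voltage in volts.
#' @export
#' @examples
#' nernst_ocp(nernst_params(E0 = 1.0, Pr = 1, Pp = 1)) # exactly E0
nernst_ocp <- function(params) {
  stopifnot(inherits(params, "nernst_params"))
  params$E0 + (.R_GAS * params$T) / (params$n * .FARADAY) *
    log(params$Pr / params$Pp)
}
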