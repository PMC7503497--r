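# Transition-state-theory arithmetic linking activation free energies and
# rate constants, plus the bundled reference energetics of the aqueous
# hydride-abstraction reaction for the two propargylamine MAO-B
# inhibitors.

.reference_table <- function() {
  data.frame(
    inhibitor = c("rasagiline", "selegiline"),
    dg_reactant = c(0.0, 0.0),
    dg_ts = c(30.60, 31.11),
    dg_intermediate = c(19.18, 17.29),
    h_ij_ref = c(44.34, 43.59),
    alpha0_ref = c(106.7, 80.40),
    k_inact_per_min = c(0.0533, 0.99),
    nu_imag_cm = c(1351, 1390),
    stringsAsFactors = FALSE)
}

#' Reference aqueous-phase energetics and inactivation kinetics
#'
#' Bundled reference data for the hydride abstraction from rasagiline and
#' selegiline by the flavin model compound in water: relative free
#' energies of the transition state and the carbocation intermediate
#' (kcal/mol, reactant complex at 0), the reference-fitted EVB coupling
#' and solution-phase shift (kcal/mol), the experimental inactivation rate
#' constants (1/min) and the imaginary frequency magnitudes (1/cm,
#' metadata).  Note the fitted `h_ij_ref`/`alpha0_ref` belong to the
#' all-atom aqueous reference model; a toy system calibrated against the
#' same free-energy targets will generally fit different parameter values.
#'
#' @param inhibitor optional id (`"rasagiline"` or `"selegiline"`); when
#'   given, returns that single row as a list.
#' @return the full reference data frame, or one record as a list.
#' @export
reference_energetics <- function(inhibitor = NULL) {
  tab <- .reference_table()
  if (is.null(inhibitor)) return(tab)
  i <- match(tolower(inhibitor), tab$inhibitor)
  if (is.na(i))
    .stopf("unknown inhibitor '%s' (expected rasagiline or selegiline)",
           inhibitor, class = "evbfep_key_error")
  as.list(tab[i, ])
}

#' Eyring rate from an activation free energy, and its inverse
#'
#' `k = (kB T / h) exp(-dg_act / (R T))` with transmission coefficient 1;
#' `barrier_from_rate()` is the exact inverse.  The `kB T / h` prefactor
#' is computed from CODATA constants at call time.
#'
#' @param dg_act activation free energy, kcal/mol.
#' @param temperature K (> 0).
#' @return rate constant in 1/s.
#' @export
eyring_rate <- function(dg_act, temperature = 298.15) {
  if (any(temperature <= 0))
    .stopf("temperature must be positive", class = "evbfep_domain_error")
  (.KB_SI * temperature / .H_SI) * exp(-dg_act / (.GAS_R * temperature))
}

#' @rdname eyring_rate
#' @param k rate constant in 1/s (> 0).
#' @return activation free energy in kcal/mol.
#' @export
barrier_from_rate <- function(k, temperature = 298.15) {
  if (any(k <= 0) || any(temperature <= 0))
    .stopf("rate and temperature must be positive",
           class = "evbfep_domain_error")
  .GAS_R * temperature * log(.KB_SI * temperature / .H_SI / k)
}

#' Activation free-energy difference implied by two rate constants
#'
#' `R T ln(k_fast / k_slow)`: the barrier advantage of the faster process.
#' Units of the two rates must match (the ratio is unit-free); `"per_min"`
#' and `"per_s"` are accepted.
#'
#' @param k_fast,k_slow positive rate constants.
#' @param temperature K.
#' @param unit_fast,unit_slow `"per_s"` or `"per_min"`.
#' @return activation free-energy difference in kcal/mol (negative when
#'   `k_fast < k_slow`).
#' @export
ddg_from_rates <- function(k_fast, k_slow, temperature = 298.15,
                           unit_fast = "per_s", unit_slow = unit_fast) {
  units <- c("per_s", "per_min")
  if (!(unit_fast %in% units) || !(unit_slow %in% units))
    .stopf("rate units must be per_s or per_min", class = "evbfep_unit_error")
  if (unit_fast != unit_slow)
    .stopf("rate unit mismatch: %s vs %s", unit_fast, unit_slow,
           class = "evbfep_unit_error")
  if (any(k_fast <= 0) || any(k_slow <= 0))
    .stopf("rates must be positive", class = "evbfep_domain_error")
  .GAS_R * temperature * log(k_fast / k_slow)
}

#' Catalytic rate enhancement in orders of magnitude
#'
#' `(dg_ref - dg_cat) / (R T ln 10)`: how many factors of ten a barrier
#' reduction from `dg_ref` to `dg_cat` buys at temperature `T` under TST.
#' Sign is preserved (negative = anticatalysis).
#'
#' @param dg_ref reference (uncatalysed) activation free energy, kcal/mol.
#' @param dg_cat catalysed activation free energy, kcal/mol.
#' @param temperature K (> 0).
#' @return orders of magnitude, unitless.
#' @export
catalytic_orders <- function(dg_ref, dg_cat, temperature = 298.15) {
  if (any(temperature <= 0))
    .stopf("temperature must be positive", class = "evbfep_domain_error")
  (dg_ref - dg_cat) / (.GAS_R * temperature * log(10))
}
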