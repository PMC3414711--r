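#' Equilibrium constant of a hydration step from its thermochemistry
#'
#' For the clustering step adding the n-th water to a cationized base, the
#' dimensionless equilibrium constant referenced to `P_STANDARD` is
#' K(T) = exp(-dH/(R T) + dS/R).
#'
#' @param dH Standard association enthalpy, kJ/mol (negative for exothermic
#'   attachment).
#' @param dS Standard association entropy, J/(mol K).
#' @param temperature Temperature, K. Must be positive.
#' @return Dimensionless equilibrium constant (vectorised over temperature).
#' @export
equilibrium_constant_from_thermo <- function(dH, dS, temperature) {
  stopifnot(is.numeric(dH), is.numeric(dS), is.numeric(temperature))
  if (any(temperature <= 0)) {
    stop("temperature must be positive (kelvin)", call. = FALSE)
  }
  exp(-dH * 1000 / (R_GAS * temperature) + dS / R_GAS)
}

#' Equilibrium intensity ratio implied by step thermochemistry
#'
#' The observable at equilibrium is the intensity ratio
#' r_n = I_n / I_{n-1} = K_n * P / P_o, with P the water partial pressure
#' and P_o = 1000 mbar. This is the stationary population ratio the
#' kinetic simulator must reproduce.
#'
#' @inheritParams equilibrium_constant_from_thermo
#' @param conditions A [cell_conditions()] object supplying `temperature`
#'   and `water_pressure`.
#' @return Dimensionless ratio r_n.
#' @export
equilibrium_ratio_from_thermo <- function(dH, dS, conditions) {
  stopifnot(inherits(conditions, "cell_conditions"))
  K <- equilibrium_constant_from_thermo(dH, dS, conditions$temperature)
  K * conditions$water_pressure / P_STANDARD
}

#' Standard Gibbs free energy from enthalpy and entropy
#'
#' dG = dH - T * dS with units reconciled (dS in J/(mol K) is converted to
#' kJ). Uncertainty is propagated to first order including the
#' enthalpy-entropy covariance from the van't Hoff fit:
#' var(dG) = var(dH) + (T/1000)^2 var(dS) - 2 (T/1000) cov(dH, dS).
#'
#' @param dH Enthalpy, kJ/mol.
#' @param dS Entropy, J/(mol K).
#' @param temperature Temperature, K (default 298.15).
#' @param sd_dH,sd_dS 1-sigma uncertainties of `dH` (kJ/mol) and `dS`
#'   (J/(mol K)); default 0.
#' @param cov_dH_dS Covariance of the two, (kJ/mol)(J/(mol K)); default 0.
#' @return A list with `value` (kJ/mol) and `sd` (kJ/mol).
#' @seealso [gibbs()] for the method on fitted `thermo_result` objects.
#' @export
gibbs_energy <- function(dH, dS, temperature = T_REPORT,
                         sd_dH = 0, sd_dS = 0, cov_dH_dS = 0) {
  if (any(temperature <= 0)) {
    stop("temperature must be positive (kelvin)", call. = FALSE)
  }
  tk <- temperature / 1000      # converts J/(mol K) to kJ/mol per kelvin
  value <- dH - temperature * dS / 1000
  var_g <- sd_dH^2 + tk^2 * sd_dS^2 - 2 * tk * cov_dH_dS
  list(value = value, sd = sqrt(pmax(var_g, 0)))
}

# Round-half-even at `digits` decimals, with ties resolved on the decimal
# representation rather than the binary one (so 29.95 -> 30.0 at 1 digit).
round_half_even <- function(x, digits = 1) {
  scaled <- x * 10^digits
  # kill representation noise before deciding whether we sit on a tie
  scaled <- round(scaled, 6)
  frac <- scaled - floor(scaled)
  tie <- abs(frac - 0.5) < 1e-6
  out <- round(scaled)          # base round is half-even away from fp noise
  lo <- floor(scaled[tie])
  out[tie] <- ifelse(lo %% 2 == 0, lo, lo + 1)
  out / 10^digits
}

# "62.3(2)" style: value at one decimal, 1-sigma as last-digit integer.
format_value_sigma <- function(value, sd, digits = 1) {
  v <- round_half_even(value, digits)
  u <- as.integer(round(sd * 10^digits))
  sprintf("%.*f(%d)", digits, v, u)
}
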