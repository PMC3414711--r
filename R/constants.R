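#' Physical constants and unit conventions
#'
#' All thermochemistry in this package uses: temperature in kelvin, pressure
#' in mbar, enthalpy in kJ/mol, entropy in J/(mol K). Association quantities
#' are stored with their thermodynamic sign (negative for exothermic water
#' attachment); report formatting negates them, as is conventional for
#' clustering tables.
#'
#' @format `R_GAS` is the molar gas constant, 8.314462618 J/(mol K) (CODATA
#'   2018). `P_STANDARD` is the standard pressure of the dimensionless
#'   clustering equilibrium constant, 1000 mbar.
#' @name constants
NULL

#' @rdname constants
#' @export
R_GAS <- 8.314462618

#' @rdname constants
#' @export
P_STANDARD <- 1000

# Report temperature for standard free energies (K).
T_REPORT <- 298.15
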