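# Physical constants (CODATA 2018) and energy-unit conversion.
# Internal energy convention everywhere in the package: J mol^-1.

.const <- list(
  h        = 6.62607015e-34,    # Planck constant, J s
  kB       = 1.380649e-23,      # Boltzmann constant, J K^-1
  c_cm     = 2.99792458e10,     # speed of light, cm s^-1
  N_A      = 6.02214076e23,     # Avogadro constant, mol^-1
  amu      = 1.66053906660e-27, # atomic mass unit, kg
  angstrom = 1e-10              # m
)
.const$R_gas <- .const$kB * .const$N_A  # 8.31446... J mol^-1 K^-1

.HARTREE_JMOL <- 2625.4996394799 * 1000
.KCAL_JMOL    <- 4184
.KJ_JMOL      <- 1000

.energy_units <- c("hartree", "kj/mol", "kcal/mol", "j/mol")

.unit_factor <- function(unit) {
  u <- tolower(trimws(unit))
  switch(u,
    "hartree"  = .HARTREE_JMOL,
    "kj/mol"   = .KJ_JMOL,
    "kcal/mol" = .KCAL_JMOL,
    "j/mol"    = 1,
    stop("unknown energy unit tag: '", unit, "' (expected one of ",
         paste(.energy_units, collapse = ", "), ")", call. = FALSE)
  )
}

#' Convert an energy to the internal unit (J mol^-1)
#'
#' Accepted unit tags are `"hartree"` (1 Hartree = 2625.4996394799 kJ/mol),
#' `"kj/mol"`, `"kcal/mol"` (thermochemical calorie, 1 kcal = 4.184 kJ) and
#' `"j/mol"`. Tags are case-insensitive.
#'
#' @param value numeric energy value(s) in `unit`.
#' @param unit unit tag.
#' @return energy in J mol^-1.
#' @export
#' @examples
#' energy_to_jmol(1, "hartree")
energy_to_jmol <- function(value, unit) {
  value * .unit_factor(unit)
}

#' @rdname energy_to_jmol
#' @export
jmol_to_unit <- function(value, unit) {
  value / .unit_factor(unit)
}

#' Constants used in the pKa conversion
#'
#' The pKa conversion uses the printed literals of the source protocol:
#' the ideal-gas constant as 8.314 J mol^-1 K^-1, ambient temperature
#' 298.15 K, the aqueous proton free energy -1131.44 kJ mol^-1 (an
#' experimental 298 K value), and the base-10 log conversion factor as the
#' literal 2.303 (pass `log_conversion = log(10)` for the exact value; the
#' difference is below 0.02%).
#'
#' @param R ideal-gas constant for the pKa conversion, J mol^-1 K^-1.
#' @param T_default default temperature, K.
#' @param dG_proton_sol aqueous free energy of the proton, J mol^-1.
#' @param log_conversion divisor converting a natural-log free-energy ratio
#'   to a base-10 pKa.
#' @return object of class `pka_constants`.
#' @export
pka_constants <- function(R = 8.314, T_default = 298.15,
                          dG_proton_sol = -1131.44e3,
                          log_conversion = 2.303) {
  stopifnot(R > 0, T_default > 0, log_conversion > 0)
  structure(list(R = R, T_default = T_default,
                 dG_proton_sol = dG_proton_sol,
                 log_conversion = log_conversion),
            class = "pka_constants")
}

#' @export
print.pka_constants <- function(x, ...) {
  cat("pKa conversion constants:\n")
  cat(sprintf("  R              %.4f J/mol/K\n", x$R))
  cat(sprintf("  T (default)    %.2f K\n", x$T_default))
  cat(sprintf("  dG_H+(sol)     %.2f kJ/mol\n", x$dG_proton_sol / 1000))
  cat(sprintf("  log conversion %.6f\n", x$log_conversion))
  invisible(x)
}
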