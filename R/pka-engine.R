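# Deprotonation free energies and pKa: direct (solution-phase free
# energies) and indirect (thermodynamic cycle through the gas phase),
# plus solvation-protocol bookkeeping.

#' Convert a deprotonation free energy to a pKa
#'
#' `pKa = dG / (log_conversion * R * T)` with the conversion constants of
#' [pka_constants()] (printed literals `2.303` and `R = 8.314` by
#' default).
#'
#' @param dG aqueous deprotonation free energy, J mol^-1.
#' @param T temperature, K.
#' @param constants a `pka_constants` object.
#' @return dimensionless pKa.
#' @export
#' @examples
#' pka_from_free_energy(40e3)  # ~7.0
pka_from_free_energy <- function(dG, T = 298.15,
                                 constants = pka_constants()) {
  if (T <= 0) stop("temperature must be positive", call. = FALSE)
  dG / (constants$log_conversion * constants$R * T)
}

#' Gas + solvation free energy
#'
#' The thermodynamic-cycle composition `G(sol) = G(gas) + dG(sol)`.
#'
#' @param G_gas gas-phase free energy, J mol^-1.
#' @param dG_solv solvation free energy, J mol^-1.
#' @return solution-phase free energy, J mol^-1.
#' @export
solution_free_energy_indirect <- function(G_gas, dG_solv) {
  G_gas + dG_solv
}

#' Build a conjugate acid/base pair model
#'
#' Pairs the protonated species (HA: an aniline radical cation or an
#' anilinium ion) with its deprotonation product (A-), together with the
#' chosen approach, correction scheme, solvation protocol and
#' explicit-water motif label. Validates the charge relation
#' `charge(A-) = charge(HA) - 1` and, unless overridden, equal
#' explicit-water counts on both sides (all supported cycles are
#' water-balanced; with `allow_water_imbalance = TRUE` a `water_record`
#' supplies the free energy of the balancing water molecules).
#'
#' @param acid protonated `species_record` (HA).
#' @param base deprotonated `species_record` (A-).
#' @param approach `"direct"` or `"indirect"` (default bookkeeping; either
#'   computation can be run on the pair).
#' @param correction `"C0"`, `"C1"` or `"C2"`.
#' @param protocol solvation protocol `"P1"`..`"P6"` (required for the
#'   indirect approach).
#' @param water_motif_label free-text motif label, e.g. `"HO-HO"`.
#' @param allow_water_imbalance allow different explicit-water counts.
#' @param water_record `species_record` of one explicit water molecule,
#'   used to balance the cycle when counts differ.
#' @return object of class `conjugate_pair`.
#' @export
conjugate_pair <- function(acid, base, approach = c("direct", "indirect"),
                           correction = c("C0", "C1", "C2"),
                           protocol = NULL, water_motif_label = NULL,
                           allow_water_imbalance = FALSE,
                           water_record = NULL) {
  approach <- match.arg(approach)
  correction <- match.arg(correction)
  stopifnot(inherits(acid, "species_record"),
            inherits(base, "species_record"))
  if (base$charge != acid$charge - 1L) {
    stop("conjugate pair charge relation violated: expected charge(A-) = ",
         "charge(HA) - 1, got ", base$charge, " and ", acid$charge,
         call. = FALSE)
  }
  if (base$explicit_waters != acid$explicit_waters &&
      !isTRUE(allow_water_imbalance)) {
    stop("explicit-water counts differ (", acid$explicit_waters, " vs ",
         base$explicit_waters, "); enable allow_water_imbalance and ",
         "supply a water_record to balance the cycle", call. = FALSE)
  }
  if (isTRUE(allow_water_imbalance) &&
      base$explicit_waters != acid$explicit_waters &&
      is.null(water_record)) {
    stop("water imbalance override requires a water_record", call. = FALSE)
  }
  if (approach == "indirect" && is.null(protocol)) {
    stop("indirect approach requires a solvation protocol (P1..P6)",
         call. = FALSE)
  }
  if (!is.null(protocol) && !protocol %in% paste0("P", 1:6)) {
    stop("unknown protocol '", protocol, "'", call. = FALSE)
  }
  if (is.null(water_motif_label)) {
    water_motif_label <- paste0(base$water_motif, "-", acid$water_motif)
  }
  structure(list(acid = acid, base = base, approach = approach,
                 correction = correction, protocol = protocol,
                 water_motif_label = water_motif_label,
                 allow_water_imbalance = isTRUE(allow_water_imbalance),
                 water_record = water_record),
            class = "conjugate_pair")
}

#' @export
print.conjugate_pair <- function(x, ...) {
  cat(sprintf("<conjugate_pair> %s / %s\n", x$acid$label, x$base$label))
  cat(sprintf("  approach %s, correction %s%s, motif %s\n", x$approach,
              x$correction,
              if (is.null(x$protocol)) "" else paste0(", protocol ", x$protocol),
              x$water_motif_label))
  invisible(x)
}

.resolve_options <- function(pair, options) {
  if (is.null(options)) options <- thermo_options(scheme = pair$correction)
  if (options$scheme != pair$correction) options$scheme <- pair$correction
  options
}

# Solution-phase G: precomputed if available, otherwise assembled from the
# (solvated-phase) electronic energy and frequencies.
.species_g_sol <- function(record, options) {
  if (!is.na(record$free_energy_sol)) return(record$free_energy_sol)
  if (!is.na(record$electronic_energy)) {
    return(gibbs_free_energy(record, options)$gibbs_total)
  }
  stop("no solution-phase free energy available for '", record$label,
       "' (need free_energy_sol or electronic_energy + frequencies)",
       call. = FALSE)
}

.species_g_gas <- function(record, options) {
  if (!is.na(record$free_energy_gas)) return(record$free_energy_gas)
  if (!is.na(record$electronic_energy)) {
    return(gibbs_free_energy(record, options)$gibbs_total)
  }
  stop("no gas-phase free energy available for '", record$label,
       "' (need free_energy_gas or electronic_energy + frequencies)",
       call. = FALSE)
}

.water_balance_term <- function(pair, options, g_of) {
  dn <- pair$acid$explicit_waters - pair$base$explicit_waters
  if (dn == 0L) return(0)
  dn * g_of(pair$water_record, options)
}

.pka_result <- function(pair, components, approach, options, constants) {
  dG <- sum(components)
  structure(list(
    dG_deprot_sol = dG,
    pKa = pka_from_free_energy(dG, options$temperature, constants),
    components = components,
    approach = approach,
    correction = pair$correction,
    protocol = pair$protocol,
    water_motif_label = pair$water_motif_label,
    temperature = options$temperature,
    constants = constants
  ), class = "pka_result")
}

#' Deprotonation free energy and pKa, direct approach
#'
#' `dG_deprot(sol) = G_A-(sol) - G_HA(sol) + dG_H+(sol)`, with each
#' species' solution-phase free energy taken from its precomputed
#' `free_energy_sol` or assembled by [gibbs_free_energy()] from a solvated
#' electronic energy and frequencies under the pair's correction scheme.
#'
#' @param pair a `conjugate_pair`.
#' @param options `thermo_options`; the scheme is forced to the pair's
#'   correction.
#' @param constants a `pka_constants` object.
#' @return object of class `pka_result` with the signed component ledger
#'   (`sum(components) == dG_deprot_sol`).
#' @export
deprotonation_direct <- function(pair, options = NULL,
                                 constants = pka_constants()) {
  stopifnot(inherits(pair, "conjugate_pair"))
  options <- .resolve_options(pair, options)
  g_a <- .species_g_sol(pair$acid, options)
  g_b <- .species_g_sol(pair$base, options)
  components <- c(G_A_sol = g_b, minus_G_HA_sol = -g_a,
                  dG_proton_sol = constants$dG_proton_sol)
  wb <- .water_balance_term(pair, options, .species_g_sol)
  if (wb != 0) components <- c(components, water_balance = wb)
  .pka_result(pair, components, "direct", options, constants)
}

#' Deprotonation free energy and pKa, indirect (thermodynamic cycle)
#'
#' `dG_deprot(sol) = [G_A-(gas) - G_HA(gas)] + [dG_A-(sol) - dG_HA(sol)]
#' + dG_H+(sol)`. Gas-phase free energies come from each species'
#' `free_energy_gas` or are assembled by [gibbs_free_energy()]; the
#' solvation free energies are looked up under the pair's protocol and the
#' protocol rules are validated via [resolve_protocol_method()].
#'
#' @inheritParams deprotonation_direct
#' @return object of class `pka_result`; the ledger carries the
#'   gas-phase terms and the `ddG_solv` difference separately.
#' @export
deprotonation_indirect <- function(pair, options = NULL,
                                   constants = pka_constants()) {
  stopifnot(inherits(pair, "conjugate_pair"))
  if (is.null(pair$protocol)) {
    stop("indirect approach requires a protocol on the pair", call. = FALSE)
  }
  options <- .resolve_options(pair, options)
  for (sp in list(pair$acid, pair$base)) {
    resolve_protocol_method(pair$protocol, sp)  # validates protocol rules
    if (is.null(sp$solvation_energies) ||
        !pair$protocol %in% names(sp$solvation_energies)) {
      stop("solvation energy for protocol ", pair$protocol,
           " missing on species '", sp$label, "'", call. = FALSE)
    }
  }
  g_a <- .species_g_gas(pair$acid, options)
  g_b <- .species_g_gas(pair$base, options)
  ds_a <- unname(pair$acid$solvation_energies[[pair$protocol]])
  ds_b <- unname(pair$base$solvation_energies[[pair$protocol]])
  components <- c(G_A_gas = g_b, minus_G_HA_gas = -g_a,
                  ddG_solv = ds_b - ds_a,
                  dG_proton_sol = constants$dG_proton_sol)
  wb <- .water_balance_term(pair, options, .species_g_sol)
  if (wb != 0) components <- c(components, water_balance = wb)
  .pka_result(pair, components, "indirect", options, constants)
}

#' @export
print.pka_result <- function(x, ...) {
  cat(sprintf("<pka_result> pKa = %.4f  [%s, %s%s]\n", x$pKa, x$approach,
              x$correction,
              if (is.null(x$protocol)) "" else paste0(", ", x$protocol)))
  cat(sprintf("  dG_deprot(sol) = %.3f kJ/mol at %.2f K\n",
              x$dG_deprot_sol / 1000, x$temperature))
  cat("  components (kJ/mol):\n")
  for (nm in names(x$components)) {
    cat(sprintf("    %-16s %14.4f\n", nm, x$components[[nm]] / 1000))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Solvation-protocol bookkeeping

.sulfonate_species <- function(species) {
  grepl("SO3", species$substituent, fixed = TRUE) ||
    grepl("SO\u2083", species$substituent)
}

.charge_class <- function(species) {
  # Class by the charge of the aniline core: a sulfonate substituent
  # carries -1 of its own, so it is added back before classifying.
  eff <- species$charge + if (.sulfonate_species(species)) 1L else 0L
  if (eff > 0) "cation" else if (eff < 0) "anion" else "neutral"
}

#' Resolve the solvation-energy method for a protocol
#'
#' Returns the electronic-structure method label a protocol prescribes for
#' a species — bookkeeping and validation only; no calculation is ever
#' launched. P1 applies one method to every species. P2 selects by charge
#' class (neutral / cation / anion), with every sulfonate-bearing species
#' routed to the anion method. P3 distinguishes the radical cation from
#' the neutral radical, again with the sulfonate special case. P4–P6 are
#' single-method explicit-water protocols and require at least one
#' explicit water on the species. Iodine-containing species carry a
#' `basis_note` attribute naming the alternate heavy-atom basis.
#'
#' @param protocol `"P1"`..`"P6"`.
#' @param species a `species_record`.
#' @return method label (character scalar), possibly with a `basis_note`
#'   attribute.
#' @export
#' @examples
#' nh2 <- species_record("PhNH2", substituent = "H", role = "deprotonated",
#'                       charge = 0, multiplicity = 1)
#' resolve_protocol_method("P2", nh2)
resolve_protocol_method <- function(protocol, species) {
  stopifnot(inherits(species, "species_record"))
  if (!protocol %in% paste0("P", 1:6)) {
    stop("unknown protocol '", protocol, "'", call. = FALSE)
  }
  sulf <- .sulfonate_species(species)
  cls <- .charge_class(species)
  method <- switch(protocol,
    P1 = "M052X/6-31G(d)",
    P2 = if (sulf || cls == "anion") "HF/6-31G(d)"
         else if (cls == "cation") "M052X/6-31+G(d,p)"
         else "M052X/6-31G(d)",
    P3 = if (!sulf && species$is_radical && cls == "cation")
           "M052X/6-31G(d)" else "HF/6-31G(d)",
    P4 = "M062X/6-31G(d)",
    P5 = "M052X/cc-pVTZ",
    P6 = "\u03c9b97xd/6-31+g(d,p)")
  if (protocol %in% c("P4", "P5", "P6") && species$explicit_waters < 1) {
    stop("protocol ", protocol, " is an explicit-water protocol but '",
         species$label, "' has no explicit waters", call. = FALSE)
  }
  heavy <- (!is.null(species$atoms) && "I" %in% species$atoms$element) ||
    identical(species$substituent, "I")
  if (heavy) {
    attr(method, "basis_note") <-
      "ma-def2QZVP basis for iodine-containing species"
  }
  method
}
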