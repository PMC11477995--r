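# Synthetic species records, conjugate pairs with known ground-truth pKa,
# and benchmark sets with known error statistics. These stand in for
# real quantum-chemistry output so every pipeline stage is testable
# without an electronic-structure run; they are labelled synthetic and do
# not mimic the force field of any real aniline.

# Run code under a fixed seed without disturbing the caller's RNG state.
.with_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

.n_modes <- function(n_atoms) {
  if (n_atoms == 1) 0L else if (n_atoms == 2) 1L else 3L * n_atoms - 6L
}

#' Specification for one synthetic species
#'
#' @param seed integer RNG seed; the generated record is a deterministic
#'   function of the spec.
#' @param n_atoms number of atoms (>= 1).
#' @param freq_range range (cm^-1) for the ordinary (non-low) modes; the
#'   lower bound must be >= 100 so low modes stay identifiable.
#' @param n_low_modes how many modes to draw below 100 cm^-1.
#' @param charge,multiplicity species charge and spin multiplicity.
#' @param explicit_waters explicit-water count carried into the record.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_atoms = 4L,
                         freq_range = c(200, 3500), n_low_modes = 0L,
                         charge = 0L, multiplicity = 1L,
                         explicit_waters = 0L) {
  stopifnot(n_atoms >= 1, length(freq_range) == 2,
            freq_range[1] >= 100, freq_range[2] > freq_range[1],
            n_low_modes >= 0, multiplicity >= 1, explicit_waters >= 0)
  n_modes <- .n_modes(n_atoms)
  if (n_low_modes > n_modes) {
    stop("n_low_modes (", n_low_modes, ") exceeds the mode count (",
         n_modes, ") for ", n_atoms, " atoms", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_atoms = as.integer(n_atoms),
                 freq_range = as.numeric(freq_range),
                 n_low_modes = as.integer(n_low_modes),
                 charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity),
                 explicit_waters = as.integer(explicit_waters)),
            class = "fixture_spec")
}

#' Generate a synthetic species record
#'
#' Draws a random non-colinear geometry (for three or more atoms), a
#' frequency list with exactly `n_low_modes` modes below 100 cm^-1 and
#' the rest inside `freq_range`, and an electronic energy in the
#' small-molecule range (-10 to -2 Hartree). Deterministic per spec.
#'
#' @param spec a `fixture_spec`.
#' @param label record label.
#' @param role `"protonated"` or `"deprotonated"`.
#' @param water_motif motif label carried into the record.
#' @return validated `species_record`.
#' @export
generate_species <- function(spec, label = paste0("synthetic-", spec$seed),
                             role = "protonated", water_motif = "") {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, function() {
    n <- spec$n_atoms
    elements <- sample(c("C", "N", "O", "H"), n, replace = TRUE)
    atoms <- atom_table(elements,
                        x = stats::runif(n, -2, 2),
                        y = stats::runif(n, -2, 2),
                        z = stats::runif(n, -2, 2))
    n_modes <- .n_modes(n)
    n_low <- min(spec$n_low_modes, n_modes)
    freqs <- c(stats::runif(n_low, 20, 99),
               stats::runif(n_modes - n_low, spec$freq_range[1],
                            spec$freq_range[2]))
    species_record(
      label = label, substituent = "synthetic", role = role,
      charge = spec$charge, multiplicity = spec$multiplicity,
      atoms = atoms, frequencies = freqs,
      electronic_energy = stats::runif(1, -10, -2),
      explicit_waters = spec$explicit_waters, water_motif = water_motif,
      energy_unit = "hartree"
    )
  })
}

#' Generate a conjugate pair with a known ground-truth pKa
#'
#' Generates an acid (charge +1, doublet — the radical-cation case) and
#' its deprotonated base, runs the thermochemistry under the requested
#' scheme, and back-solves the base's electronic energy (the single
#' linear unknown) so that the full pipeline returns exactly
#' `target_pka`. Each species also receives a consistent indirect
#' decomposition — a random solvation free energy under `protocol` and
#' `free_energy_gas = G(sol) - dG(sol)` — so the direct and
#' thermodynamic-cycle routes are both exercised and must agree.
#'
#' @param seed integer RNG seed.
#' @param target_pka the pKa the pipeline must return.
#' @param options `thermo_options` (scheme, temperature, ...).
#' @param constants `pka_constants` used in the conversion.
#' @param protocol solvation protocol attached to the indirect
#'   decomposition.
#' @param n_atoms atoms per species (kept small; 3 gives 3 modes).
#' @param n_low_modes low-frequency modes per species, to exercise the
#'   quasi-harmonic schemes.
#' @return a `conjugate_pair` ready for [deprotonation_direct()] and
#'   [deprotonation_indirect()].
#' @export
generate_pair_with_known_pka <- function(seed, target_pka,
                                         options = thermo_options(),
                                         constants = pka_constants(),
                                         protocol = "P6", n_atoms = 3L,
                                         n_low_modes = 1L) {
  stopifnot(is.finite(target_pka))
  acid <- generate_species(
    fixture_spec(seed = seed, n_atoms = n_atoms,
                 n_low_modes = n_low_modes, charge = 1L,
                 multiplicity = 2L, explicit_waters = 1L),
    label = paste0("synthetic-acid-", seed), role = "protonated",
    water_motif = "HO")
  base <- generate_species(
    fixture_spec(seed = seed + 1L, n_atoms = n_atoms,
                 n_low_modes = n_low_modes, charge = 0L,
                 multiplicity = 2L, explicit_waters = 1L),
    label = paste0("synthetic-base-", seed), role = "deprotonated",
    water_motif = "HO")

  g_acid <- gibbs_free_energy(acid, options)$gibbs_total
  g_base <- gibbs_free_energy(base, options)$gibbs_total
  dG_target <- target_pka * constants$log_conversion * constants$R *
    options$temperature
  # dG = G_base - G_acid + dG_H+; shift the base's electronic energy so
  # the cycle lands exactly on the target (G is additive in E_elec).
  shift <- dG_target - (g_base - g_acid + constants$dG_proton_sol)
  base$electronic_energy <- base$electronic_energy + shift
  g_base <- g_base + shift

  solv <- .with_seed(seed + 2L, function() stats::runif(2, -40e3, -10e3))
  acid$solvation_energies <- stats::setNames(solv[1], protocol)
  base$solvation_energies <- stats::setNames(solv[2], protocol)
  acid$free_energy_gas <- g_acid - solv[1]
  base$free_energy_gas <- g_base - solv[2]

  conjugate_pair(acid, base, approach = "direct",
                 correction = options$scheme, protocol = protocol,
                 water_motif_label = "HO-HO")
}

#' Generate a benchmark set with known error statistics
#'
#' Calculated values are the experimental per-compound averages plus
#' deterministic Gaussian noise of standard deviation `sigma`; the
#' realized RMSE is also computed by independent element-wise summation
#' and returned as ground truth. With `n_synthetic`, an arbitrary-size
#' synthetic reference table (pKa drawn uniformly in -2..14) replaces
#' the embedded one, for large-n statistical checks.
#'
#' @param seed integer RNG seed.
#' @param sigma noise standard deviation, pKa units (>= 0).
#' @param system which embedded system to use.
#' @param n_synthetic if not `NULL`, size of a synthetic reference table
#'   used instead of the embedded dataset.
#' @return list with `results` (data.frame for [benchmark_run()]),
#'   `table` (the reference table used), `ground_truth_rmse` and `sigma`.
#' @export
generate_benchmark_set <- function(seed, sigma,
                                   system = c("radical_cation", "anilinium"),
                                   n_synthetic = NULL) {
  system <- match.arg(system)
  stopifnot(sigma >= 0)
  .with_seed(seed, function() {
    if (is.null(n_synthetic)) {
      table <- experimental_pka_table(system)
    } else {
      stopifnot(n_synthetic >= 1)
      vals <- stats::runif(n_synthetic, -2, 14)
      table <- data.frame(
        substituent = paste0("S", seq_len(n_synthetic)),
        system = system, n_values = 1L, pka_exp = vals,
        stringsAsFactors = FALSE)
      table$values <- I(as.list(vals))
      table$references <- I(rep(list("synthetic"), n_synthetic))
    }
    noise <- stats::rnorm(nrow(table), mean = 0, sd = sigma)
    results <- data.frame(substituent = table$substituent,
                          system = table$system,
                          pka_calc = table$pka_exp + noise,
                          stringsAsFactors = FALSE)
    # ground truth by independent summation (not via pka_rmse)
    ss <- 0
    for (e in noise) ss <- ss + e * e
    list(results = results, table = table,
         ground_truth_rmse = sqrt(ss / length(noise)), sigma = sigma)
  })
}
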