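# Ideal-gas statistical thermochemistry: RRHO (C0) and the two
# quasi-harmonic low-frequency treatments — frequency raising (C1) and
# harmonic/free-rotor entropy interpolation (C2).

#' Thermochemistry options
#'
#' @param temperature temperature, K.
#' @param pressure pressure, Pa (1 atm default).
#' @param scheme vibrational correction scheme: `"C0"` (plain RRHO),
#'   `"C1"` (raise all frequencies below `nu0` to `nu0`), `"C2"`
#'   (harmonic/free-rotor entropy interpolation).
#' @param zpe_scale empirical zero-point-energy scale factor (applied to
#'   the raw frequencies for the ZPE under every scheme).
#' @param nu0 low-frequency threshold, cm^-1.
#' @param b_av averaged molecular moment of inertia used by the
#'   free-rotor limit of C2, kg m^2.
#' @param standard_state_correction `"off"` or `"gas1atm_to_1M"`; when
#'   enabled, `R*T*ln(24.46)` is added to each species' total free energy
#'   to move from the 1 atm gas standard state to 1 mol/L.
#' @param c1_raise_thermal logical; under C1, raise frequencies for the
#'   vibrational thermal energy as well as the entropy (the ZPE always
#'   uses raw scaled frequencies).
#' @return object of class `thermo_options`.
#' @export
thermo_options <- function(temperature = 298.15, pressure = 101325,
                           scheme = c("C0", "C1", "C2"),
                           zpe_scale = 1.0, nu0 = 100, b_av = 1e-44,
                           standard_state_correction = c("off", "gas1atm_to_1M"),
                           c1_raise_thermal = TRUE) {
  scheme <- match.arg(scheme)
  standard_state_correction <- match.arg(standard_state_correction)
  stopifnot(temperature > 0, pressure > 0, nu0 > 0, b_av > 0,
            zpe_scale > 0, zpe_scale <= 1.2)
  structure(list(temperature = temperature, pressure = pressure,
                 scheme = scheme, zpe_scale = zpe_scale, nu0 = nu0,
                 b_av = b_av,
                 standard_state_correction = standard_state_correction,
                 c1_raise_thermal = isTRUE(c1_raise_thermal)),
            class = "thermo_options")
}

#' Harmonic-oscillator terms for one vibrational mode
#'
#' For a mode of wavenumber `nu` with vibrational temperature
#' `Theta = h c nu / kB`:
#' ZPE = (1/2) N_A h c nu, U = R Theta / (exp(Theta/T) - 1),
#' S = R \[ (Theta/T)/(exp(Theta/T) - 1) - ln(1 - exp(-Theta/T)) \].
#' Vectorized over `nu`.
#'
#' @param nu wavenumber(s), cm^-1; must be positive.
#' @param T temperature, K.
#' @return list with numeric vectors `zpe`, `u` (J mol^-1) and `s`
#'   (J mol^-1 K^-1).
#' @export
vibrational_mode_terms <- function(nu, T = 298.15) {
  if (any(nu <= 0)) stop("wavenumbers must be positive", call. = FALSE)
  if (T <= 0) stop("temperature must be positive", call. = FALSE)
  theta <- .const$h * .const$c_cm * nu / .const$kB
  x <- theta / T
  zpe <- 0.5 * .const$N_A * .const$h * .const$c_cm * nu
  u <- .const$R_gas * theta / expm1(x)
  s <- .const$R_gas * (x / expm1(x) - log1p(-exp(-x)))
  list(zpe = zpe, u = u, s = s)
}

#' Translational contribution (ideal gas)
#'
#' `U = (3/2) R T`; the entropy is the Sackur–Tetrode expression
#' `S = R [ ln( (2 pi m kB T / h^2)^{3/2} kB T / P ) + 5/2 ]` with `m` the
#' molecular mass.
#'
#' @param mass molecular mass.
#' @param T temperature, K.
#' @param P pressure, Pa.
#' @param mass_unit `"amu"` (default) or `"kg"`.
#' @return list with `u` (J mol^-1) and `s` (J mol^-1 K^-1).
#' @export
translational_terms <- function(mass, T = 298.15, P = 101325,
                                mass_unit = c("amu", "kg")) {
  mass_unit <- match.arg(mass_unit)
  if (mass <= 0) stop("mass must be positive", call. = FALSE)
  m <- if (mass_unit == "amu") mass * .const$amu else mass
  u <- 1.5 * .const$R_gas * T
  q_term <- (2 * pi * m * .const$kB * T / .const$h^2)^1.5 *
    (.const$kB * T / P)
  s <- .const$R_gas * (log(q_term) + 2.5)
  list(u = u, s = s)
}

#' Rigid-rotor rotational contribution
#'
#' Monatomic species contribute nothing. A linear rotor with moment `I`
#' has `q = T / (sigma Theta_rot)`, `Theta_rot = h^2 / (8 pi^2 I kB)`,
#' `U = R T`, `S = R (ln q + 1)`. A nonlinear top uses
#' `q = (sqrt(pi)/sigma) sqrt(T^3 / (Theta_A Theta_B Theta_C))`,
#' `U = (3/2) R T`, `S = R (ln q + 3/2)`.
#'
#' @param rot `rotational_data` from [principal_moments()].
#' @param T temperature, K.
#' @return list with `u` (J mol^-1) and `s` (J mol^-1 K^-1).
#' @export
rotational_terms <- function(rot, T = 298.15) {
  stopifnot(inherits(rot, "rotational_data"), T > 0)
  sigma <- rot$symmetry_number
  I3 <- rot$principal_moments
  theta_of <- function(I) .const$h^2 / (8 * pi^2 * I * .const$kB)
  if (rot$linearity == "monatomic") {
    return(list(u = 0, s = 0))
  }
  if (rot$linearity == "linear") {
    I <- mean(I3[2:3])
    q <- T / (sigma * theta_of(I))
    return(list(u = .const$R_gas * T,
                s = .const$R_gas * (log(q) + 1)))
  }
  if (any(I3 <= 0)) {
    stop("nonlinear species with a zero principal moment", call. = FALSE)
  }
  q <- sqrt(pi) / sigma * sqrt(T^3 / prod(theta_of(I3)))
  list(u = 1.5 * .const$R_gas * T,
       s = .const$R_gas * (log(q) + 1.5))
}

#' Raise low frequencies to a threshold
#'
#' Implements the frequency-raising quasi-harmonic rule: every frequency
#' below `nu0` is replaced by `nu0` (element-wise `max`), order preserved.
#'
#' @param freqs wavenumbers, cm^-1 (all positive).
#' @param nu0 threshold, cm^-1.
#' @return raised frequencies.
#' @export
#' @examples
#' raised_frequencies(c(50, 120, 99.9), 100)
raised_frequencies <- function(freqs, nu0 = 100) {
  if (any(freqs <= 0)) stop("wavenumbers must be positive", call. = FALSE)
  pmax(freqs, nu0)
}

#' Interpolated mode entropy (harmonic / free rotor)
#'
#' The damped entropy of one mode: a weight `w = 1 / (1 + (nu0/nu)^4)`
#' interpolates between the harmonic-oscillator entropy and the entropy of
#' a free rotor of effective moment `mu = h / (8 pi^2 c nu)`, reduced
#' against an averaged molecular moment `b_av` via
#' `mu' = mu b_av / (mu + b_av)`:
#' `S_FR = R [ 1/2 + ln( sqrt(8 pi^3 mu' kB T / h^2) ) ]`,
#' result `w S_HO + (1 - w) S_FR`. Vectorized over `nu`.
#'
#' @param nu wavenumber(s), cm^-1; must be positive.
#' @param T temperature, K.
#' @param nu0 interpolation midpoint, cm^-1.
#' @param b_av averaged molecular moment, kg m^2.
#' @return entropy, J mol^-1 K^-1.
#' @export
grimme_mode_entropy <- function(nu, T = 298.15, nu0 = 100, b_av = 1e-44) {
  if (any(nu <= 0)) stop("wavenumbers must be positive", call. = FALSE)
  w <- 1 / (1 + (nu0 / nu)^4)
  s_ho <- vibrational_mode_terms(nu, T)$s
  mu <- .const$h / (8 * pi^2 * .const$c_cm * nu)
  mu_p <- mu * b_av / (mu + b_av)
  s_fr <- .const$R_gas *
    (0.5 + log(sqrt(8 * pi^3 * mu_p * .const$kB * T / .const$h^2)))
  w * s_ho + (1 - w) * s_fr
}

#' Gibbs free energy of a species from its QC results
#'
#' Assembles the ideal-gas Gibbs free energy from the electronic energy,
#' harmonic frequencies and geometry of a species record:
#' `G = E_elec + ZPE + U_trans + U_rot + U_vib + RT - T (S_trans + S_rot +
#' S_vib + S_elec)`, with `S_elec = R ln(multiplicity)`. The ZPE always
#' uses the raw (scaled) frequencies; the scheme decides the vibrational
#' thermal energy and entropy: C0 uses the harmonic formulas on raw
#' frequencies, C1 raises frequencies below `nu0` first, C2 keeps the
#' harmonic thermal energy and replaces the mode entropy by the
#' harmonic/free-rotor interpolation.
#'
#' @param record a `species_record` with electronic energy, geometry and
#'   (unless monatomic) frequencies.
#' @param options a `thermo_options` object.
#' @return object of class `thermo_result` with the full component
#'   breakdown (all energies J mol^-1, entropies J mol^-1 K^-1).
#' @export
gibbs_free_energy <- function(record, options = thermo_options()) {
  stopifnot(inherits(record, "species_record"),
            inherits(options, "thermo_options"))
  if (is.null(record$atoms) || nrow(record$atoms) == 0) {
    stop("gibbs_free_energy requires a geometry (atoms)", call. = FALSE)
  }
  if (is.na(record$electronic_energy)) {
    stop("record '", record$label, "' has no electronic_energy",
         call. = FALSE)
  }
  n <- nrow(record$atoms)
  freqs <- record$frequencies
  if (n > 1 && length(freqs) == 0) {
    stop("polyatomic record '", record$label, "' has no frequencies",
         call. = FALSE)
  }
  if (any(freqs <= 0)) {
    stop("record '", record$label, "' carries non-positive frequencies; ",
         "run validate_species_record(allow_imaginary = \"drop\") first",
         call. = FALSE)
  }
  T <- options$temperature
  R <- .const$R_gas

  rot <- principal_moments(record$atoms,
                           symmetry_number = record$symmetry_number)
  if (record$linearity != "auto" && rot$linearity != "monatomic") {
    rot$linearity <- record$linearity
  }

  tr <- translational_terms(sum(record$atoms$mass), T, options$pressure)
  ro <- rotational_terms(rot, T)

  if (length(freqs) > 0) {
    zpe <- sum(vibrational_mode_terms(options$zpe_scale * freqs, T)$zpe)
    u_freqs <- switch(options$scheme,
      C0 = freqs,
      C1 = if (options$c1_raise_thermal)
             raised_frequencies(freqs, options$nu0) else freqs,
      C2 = freqs)
    u_vib <- sum(vibrational_mode_terms(u_freqs, T)$u)
    s_vib <- switch(options$scheme,
      C0 = sum(vibrational_mode_terms(freqs, T)$s),
      C1 = sum(vibrational_mode_terms(
             raised_frequencies(freqs, options$nu0), T)$s),
      C2 = sum(grimme_mode_entropy(freqs, T, options$nu0, options$b_av)))
  } else {
    zpe <- 0; u_vib <- 0; s_vib <- 0
  }

  s_elec <- R * log(record$multiplicity)
  enthalpy_correction <- zpe + tr$u + ro$u + u_vib + R * T
  s_total <- tr$s + ro$s + s_vib + s_elec
  gibbs_correction <- enthalpy_correction - T * s_total
  ss_term <- if (options$standard_state_correction == "gas1atm_to_1M")
    R * T * log(24.46) else 0
  gibbs_total <- record$electronic_energy + gibbs_correction + ss_term

  structure(list(
    zpe = zpe, u_trans = tr$u, u_rot = ro$u, u_vib = u_vib,
    s_trans = tr$s, s_rot = ro$s, s_vib = s_vib, s_elec = s_elec,
    enthalpy_correction = enthalpy_correction,
    gibbs_correction = gibbs_correction,
    standard_state_term = ss_term,
    gibbs_total = gibbs_total,
    electronic_energy = record$electronic_energy,
    scheme = options$scheme, temperature = T, pressure = options$pressure,
    label = record$label
  ), class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  kj <- function(v) v / 1000
  cat(sprintf("<thermo_result> %s  [scheme %s, %.2f K]\n",
              x$label, x$scheme, x$temperature))
  cat(sprintf("  ZPE              %10.3f kJ/mol\n", kj(x$zpe)))
  cat(sprintf("  U trans/rot/vib  %10.3f / %.3f / %.3f kJ/mol\n",
              kj(x$u_trans), kj(x$u_rot), kj(x$u_vib)))
  cat(sprintf("  S trans/rot/vib/elec %8.3f / %.3f / %.3f / %.3f J/mol/K\n",
              x$s_trans, x$s_rot, x$s_vib, x$s_elec))
  cat(sprintf("  H correction     %10.3f kJ/mol\n",
              kj(x$enthalpy_correction)))
  cat(sprintf("  G correction     %10.3f kJ/mol\n", kj(x$gibbs_correction)))
  cat(sprintf("  G total          %14.6f kJ/mol\n", kj(x$gibbs_total)))
  invisible(x)
}
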