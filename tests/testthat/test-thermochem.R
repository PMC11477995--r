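# Statistical-thermodynamic closed forms and the three correction schemes.

test_that("harmonic mode terms match the closed form and its limits", {
  # hand value: nu = 100 cm^-1 has Theta = 143.88 K; S = 14.45 J/mol/K
  s100 <- vibrational_mode_terms(100, 298.15)$s
  expect_equal(s100, 14.45, tolerance = 2e-3)

  # term-by-term oracle on random modes and temperatures
  set.seed(7)
  for (i in 1:100) {
    nu <- runif(1, 5, 4000)
    T <- runif(1, 150, 600)
    got <- vibrational_mode_terms(nu, T)
    want <- oracle_mode(nu, T)
    expect_equal(got$zpe, want$zpe, tolerance = 1e-12)
    expect_equal(got$u, want$u, tolerance = 1e-9)
    expect_equal(got$s, want$s, tolerance = 1e-9)
  }

  # stiff-mode limit: U and S vanish
  stiff <- vibrational_mode_terms(1e6, 298.15)
  expect_lt(stiff$u, 1e-300)
  expect_lt(stiff$s, 1e-300)

  # monotonicity: S strictly decreasing in nu
  nus <- seq(10, 4000, length.out = 200)
  expect_true(all(diff(vibrational_mode_terms(nus, 298.15)$s) < 0))

  expect_error(vibrational_mode_terms(-10), "positive")
})

test_that("translational terms follow Sackur-Tetrode exactly", {
  got <- translational_terms(39.948, 298.15, 101325)
  expect_equal(got$s, oracle_trans_s(39.948, 298.15, 101325),
               tolerance = 1e-12)
  # cross-check against the published argon standard entropy (1 bar value)
  expect_equal(translational_terms(39.948, 298.15, 1e5)$s, 154.846,
               tolerance = 1e-4)

  # U = 3/2 RT doubles with T; pressure term is -R ln 2
  expect_equal(translational_terms(39.948, 2 * 298.15)$u,
               2 * translational_terms(39.948, 298.15)$u)
  expect_equal(translational_terms(39.948, 298.15, 2 * 101325)$s -
                 translational_terms(39.948, 298.15, 101325)$s,
               -ORA$R * log(2), tolerance = 1e-12)
  expect_error(translational_terms(0), "positive")
})

test_that("rotational terms: monatomic, symmetry number, closed-form linear rotor", {
  mono <- principal_moments(atom_table("Ar", 0, 0, 0))
  expect_equal(rotational_terms(mono, 298.15), list(u = 0, s = 0))

  atoms <- make_bent_triatomic()
  r1 <- principal_moments(atoms, symmetry_number = 1)
  r2 <- principal_moments(atoms, symmetry_number = 2)
  s1 <- rotational_terms(r1, 298.15)$s
  s2 <- rotational_terms(r2, 298.15)$s
  expect_equal(s2 - s1, -ORA$R * log(2), tolerance = 1e-12)

  # linear rotor with the hand-computed diatomic moment
  dia <- atom_table(c("H", "H"), x = c(0, 0), y = c(0, 0),
                    z = c(-0.5, 0.5), mass = c(1, 1))
  rot <- principal_moments(dia)
  got <- rotational_terms(rot, 298.15)
  want <- oracle_rot(rot$principal_moments, 1, 298.15, linear = TRUE)
  expect_equal(got$s, want$s, tolerance = 1e-10)
  expect_equal(got$u, want$u, tolerance = 1e-12)

  # nonlinear oracle on random fixtures
  set.seed(11)
  for (i in 1:100) {
    n <- sample(3:6, 1)
    a <- atom_table(sample(c("C", "O", "H"), n, replace = TRUE),
                    runif(n, -2, 2), runif(n, -2, 2), runif(n, -2, 2))
    rot <- principal_moments(a)
    T <- runif(1, 200, 400)
    got <- rotational_terms(rot, T)
    want <- oracle_rot(rot$principal_moments, 1, T,
                       linear = rot$linearity == "linear")
    expect_equal(got$s, want$s, tolerance = 1e-9)
    expect_equal(got$u, want$u, tolerance = 1e-12)
  }

  broken <- structure(list(principal_moments = c(0, 1e-47, 1e-47),
                           linearity = "nonlinear", symmetry_number = 1L),
                      class = "rotational_data")
  expect_error(rotational_terms(broken), "zero principal moment")
})

test_that("frequency raising is an element-wise max that preserves order", {
  expect_equal(raised_frequencies(c(50, 120, 99.9), 100), c(100, 120, 100))
  expect_equal(raised_frequencies(c(150, 300), 100), c(150, 300))
  expect_equal(raised_frequencies(100, 100), 100)  # boundary not raised
  expect_error(raised_frequencies(c(-5, 100)), "positive")
})

test_that("interpolated mode entropy hits midpoint, harmonic and free-rotor limits", {
  # at nu = nu0 the weight is exactly 1/2
  s_mid <- grimme_mode_entropy(100, 298.15, 100, 1e-44)
  s_ho <- vibrational_mode_terms(100, 298.15)$s
  s_fr <- oracle_free_rotor_s(100, 298.15, 1e-44)
  expect_equal(s_mid, 0.5 * s_ho + 0.5 * s_fr, tolerance = 1e-12)

  # high-frequency limit: the harmonic weight is 1 - 1.2e-6 at 3000 and
  # the deviation from the harmonic entropy is absolutely negligible
  # (S_HO itself tends to zero there, so a relative bound is meaningless)
  expect_equal(1 / (1 + (100 / 3000)^4), 1 - 1.234568e-6,
               tolerance = 1e-6)
  expect_lt(abs(grimme_mode_entropy(3000, 298.15) -
                  vibrational_mode_terms(3000, 298.15)$s), 1e-5)

  # low-frequency limit: within 1e-4 relative of the free rotor
  expect_equal(grimme_mode_entropy(10, 298.15),
               oracle_free_rotor_s(10, 298.15, 1e-44),
               tolerance = 1e-4)

  expect_error(grimme_mode_entropy(0), "positive")
})

test_that("scheme relations: C0 = C1 above the threshold; C1 bounded; C2 -> C0", {
  rec_hi <- species_record("hi", atoms = make_bent_triatomic(),
                           frequencies = c(150, 1600, 3650),
                           electronic_energy = -76, energy_unit = "hartree")
  g0 <- gibbs_free_energy(rec_hi, thermo_options(scheme = "C0"))
  g1 <- gibbs_free_energy(rec_hi, thermo_options(scheme = "C1"))
  expect_identical(g0$gibbs_total, g1$gibbs_total)
  expect_identical(g0$s_vib, g1$s_vib)

  # below the threshold, C1's per-mode entropy equals C0 evaluated at nu0
  s_c1 <- vibrational_mode_terms(raised_frequencies(12, 100), 298.15)$s
  expect_equal(s_c1, vibrational_mode_terms(100, 298.15)$s)

  # C0 diverges as nu -> 0+ while C1 and C2 stay bounded
  tiny <- c(1e-3, 1e-2, 0.1, 1)
  s_c0 <- vibrational_mode_terms(tiny, 298.15)$s
  expect_gt(s_c0[1], 100)
  s_c1 <- vibrational_mode_terms(raised_frequencies(tiny, 100), 298.15)$s
  s_c2 <- grimme_mode_entropy(tiny, 298.15)
  expect_true(all(s_c1 < 15))
  expect_true(all(is.finite(s_c2)) && all(s_c2 < 60))

  # per-mode C2 -> C0 as nu -> infinity (absolute convergence)
  expect_lt(abs(grimme_mode_entropy(8000, 298.15) -
                  vibrational_mode_terms(8000, 298.15)$s), 2e-7)
})

test_that("gibbs assembly satisfies its identity and additivity on random fixtures", {
  set.seed(23)
  for (scheme in c("C0", "C1", "C2")) {
    for (i in 1:10) {
      rec <- generate_species(fixture_spec(seed = 1000 + i, n_atoms = 4,
                                           n_low_modes = 2,
                                           multiplicity = sample(1:3, 1)))
      opt <- thermo_options(scheme = scheme)
      g <- gibbs_free_energy(rec, opt)
      s_total <- g$s_trans + g$s_rot + g$s_vib + g$s_elec
      expect_gt(s_total, 0)
      expect_equal(g$gibbs_correction,
                   g$zpe + g$u_trans + g$u_rot + g$u_vib +
                     ORA$R * 298.15 - 298.15 * s_total,
                   tolerance = 1e-12)
      expect_equal(g$enthalpy_correction,
                   g$zpe + g$u_trans + g$u_rot + g$u_vib + ORA$R * 298.15,
                   tolerance = 1e-12)

      # shifting E_elec shifts G by exactly the same amount
      shifted <- rec
      shifted$electronic_energy <- rec$electronic_energy + 12345.6
      g2 <- gibbs_free_energy(shifted, opt)
      expect_equal(g2$gibbs_total - g$gibbs_total, 12345.6,
                   tolerance = 1e-6)
    }
  }
})

test_that("monatomic free energy reduces to translation + electronic terms", {
  rec <- species_record("argon", atoms = atom_table("Ar", 0, 0, 0),
                        electronic_energy = -527.5, energy_unit = "hartree")
  g <- gibbs_free_energy(rec, thermo_options())
  T <- 298.15
  s_exp <- oracle_trans_s(39.948, T, 101325)
  expect_equal(g$s_trans, s_exp, tolerance = 1e-10)
  expect_equal(g$gibbs_correction,
               1.5 * ORA$R * T + ORA$R * T - T * s_exp, tolerance = 1e-10)
  expect_equal(g$zpe, 0)
  expect_equal(g$u_rot, 0)

  # open-shell monatomic: S_elec = R ln 2
  rad <- suppressWarnings(species_record(
    "radical-atom", atoms = atom_table("I", 0, 0, 0), multiplicity = 2,
    electronic_energy = -6918, energy_unit = "hartree"))
  g2 <- gibbs_free_energy(rad, thermo_options())
  expect_equal(g2$s_elec, ORA$R * log(2), tolerance = 1e-12)
})

test_that("diatomic Gibbs free energy matches a hand-summed term-by-term oracle", {
  # one mode at 500 cm^-1, C-O style diatomic at 1.128 A
  atoms <- atom_table(c("C", "O"), x = c(0, 0), y = c(0, 0),
                      z = c(0, 1.128))
  rec <- species_record("co-like", atoms = atoms, frequencies = 500,
                        electronic_energy = -113.3, energy_unit = "hartree",
                        linearity = "linear")
  T <- 298.15
  g <- gibbs_free_energy(rec, thermo_options(scheme = "C0"))

  mode <- oracle_mode(500, T)
  tr_s <- oracle_trans_s(12.011 + 15.999, T, 101325)
  rot <- oracle_rot(principal_moments(atoms)$principal_moments, 1, T,
                    linear = TRUE)
  g_corr <- mode$zpe + 1.5 * ORA$R * T + rot$u + mode$u + ORA$R * T -
    T * (tr_s + rot$s + mode$s + 0)
  expect_equal(g$gibbs_correction, g_corr, tolerance = 1e-9)
  expect_equal(g$gibbs_total, -113.3 * 2625.4996394799e3 + g_corr,
               tolerance = 1e-9)
})

test_that("ZPE scaling and the standard-state option act where documented", {
  rec <- species_record("hi", atoms = make_bent_triatomic(),
                        frequencies = c(80, 1600, 3650),
                        electronic_energy = -76, energy_unit = "hartree")
  g1 <- gibbs_free_energy(rec, thermo_options(scheme = "C1",
                                              zpe_scale = 0.97))
  g1_raw <- gibbs_free_energy(rec, thermo_options(scheme = "C1"))
  # ZPE scales linearly; raising never touches the ZPE
  expect_equal(g1$zpe, 0.97 * g1_raw$zpe, tolerance = 1e-12)
  expect_identical(g1$s_vib, g1_raw$s_vib)

  gss <- gibbs_free_energy(rec, thermo_options(
    standard_state_correction = "gas1atm_to_1M"))
  g0 <- gibbs_free_energy(rec, thermo_options())
  expect_equal(gss$gibbs_total - g0$gibbs_total,
               ORA$R * 298.15 * log(24.46), tolerance = 1e-9)
  # the correction identity itself is untouched
  expect_equal(gss$gibbs_correction, g0$gibbs_correction)
})
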