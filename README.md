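# qcpka

Aqueous pKa prediction for para-substituted aniline radical cations
(R-PhNH₂•⁺) and anilinium ions (R-PhNH₃⁺) from quantum-chemistry output.

Aniline radical cations form when the electron-rich amino group is
oxidized in natural waters; whether they deprotonate at environmental pH
is governed by their pKa, which is hard to measure for such short-lived
species. `qcpka` is the post-processing half of a computational pKa
protocol: you bring per-species electronic-structure results (electronic
energy, harmonic frequencies, geometry, optional solvation free
energies), and the package turns them into deprotonation free energies
and pKa values, benchmarks them against an embedded experimental dataset,
and bookkeeps the solvation protocol and explicit-water model used. It
never launches an electronic-structure calculation itself.

## The model

The pKa follows from the aqueous deprotonation free energy

    pKa = ΔG_deprot(sol) / (2.303 · R · T),      R = 8.314 J mol⁻¹ K⁻¹, T = 298.15 K

computed either **directly** from solution-phase free energies,

    ΔG_deprot(sol) = G_A⁻(sol) − G_HA(sol) + ΔG_H⁺(sol),   ΔG_H⁺(sol) = −1131.44 kJ mol⁻¹

or **indirectly** through a thermodynamic cycle via the gas phase,

    G(sol) = G(gas) + ΔG(sol)
    ΔG_deprot(sol) = [G_A⁻(gas) − G_HA(gas)] + [ΔG_A⁻(sol) − ΔG_HA(sol)] + ΔG_H⁺(sol)

where the per-species solvation energies ΔG(sol) are looked up under one
of six protocols (P1–P6) that select the electronic-structure method by
charge class, radical character and the sulfonate special case; P4–P6
require explicit-water cluster models.

Free energies are assembled by ideal-gas statistical thermochemistry
(`gibbs_free_energy()`) under three vibrational treatments:

* **C0** — plain rigid-rotor harmonic oscillator (RRHO);
* **C1** — quasi-RRHO by raising every frequency below 100 cm⁻¹ to
  100 cm⁻¹;
* **C2** — quasi-RRHO by interpolating each mode's entropy between the
  harmonic oscillator and a free rotor,
  `S = w·S_HO + (1−w)·S_FR`, `w = 1/(1 + (ν₀/ν)⁴)`.

Benchmarking (`benchmark_run()`) reports per-compound ΔpKa, RMSE,
RMSE mean ± SD across method combinations, and the calculated-vs-
experimental regression (slope, intercept, r²), against the embedded
literature table of 10 substituents × 2 systems.

## Worked example

A synthetic conjugate pair with known ground-truth pKa 7.30 ships with
the package (generated by `generate_pair_with_known_pka()`; it exercises
the full pipeline without any quantum-chemistry run):

```r
library(qcpka)
dir  <- system.file("extdata", "synthetic-pair", package = "qcpka")
acid <- read_species_record(file.path(dir, "acid.json"))
base <- read_species_record(file.path(dir, "base.json"))
pair <- conjugate_pair(acid, base, correction = "C0", protocol = "P6")
deprotonation_direct(pair)
#> <pka_result> pKa = 7.3000  [direct, C0, P6]
#>   dG_deprot(sol) = 41.674 kJ/mol at 298.15 K
#>   components (kJ/mol):
#>     G_A_sol             -13060.4703
#>     minus_G_HA_sol       14233.5840
#>     dG_proton_sol        -1131.4400
```

The component ledger shows the two solution-phase free energies and the
proton term; their sum is the 41.674 kJ/mol deprotonation free energy,
and dividing by 2.303·R·T gives pKa 7.30. `deprotonation_indirect(pair)`
returns the same value through the gas-phase cycle — the two routes are
algebraically identical when the inputs are consistent.

The same computation is available from a shell:

```sh
Rscript inst/cli/pka.R compute --pair inst/extdata/synthetic-pair/pair.json \
    --approach direct --out result.json
```

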