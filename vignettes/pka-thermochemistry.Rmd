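---
title: "Computing aqueous pKa from quantum-chemistry output"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing aqueous pKa from quantum-chemistry output}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcpka)
```

## The problem

Para-substituted aniline radical cations (R-PhNH₂•⁺) are transient
one-electron oxidation products whose acid–base behaviour controls their
fate in natural waters: their pKa (average literature value 7.3) sits
inside the environmental pH range, unlike the stable anilinium ions
(R-PhNH₃⁺, average about 3.9). Measuring pKa for species that live for
microseconds is costly, so one computes it: optimize the protonated and
deprotonated species in a continuum solvent (optionally with a few
explicit water molecules hydrogen-bonded to the amino group), obtain
free energies, and convert the deprotonation free energy to a pKa.

`qcpka` implements everything downstream of the electronic-structure
code: statistical thermochemistry, the free-energy bookkeeping of the
direct and thermodynamic-cycle routes, protocol and water-model
metadata, and the benchmark statistics used to rank method
combinations. Running Gaussian-style calculations, geometry
optimization, and the automated placement of explicit waters are out of
scope by design.

## Free-energy assembly

For each species the Gibbs free energy is

$$G = E_\mathrm{elec} + \mathrm{ZPE} + U_\mathrm{trans} + U_\mathrm{rot}
  + U_\mathrm{vib} + RT - T\,(S_\mathrm{trans} + S_\mathrm{rot}
  + S_\mathrm{vib} + S_\mathrm{elec})$$

with the classic ideal-gas closed forms: Sackur–Tetrode translation,
rigid-rotor rotation from the principal moments of inertia (computed
from the Cartesian geometry; the symmetry number defaults to 1 and is
user-supplied, since published protocols rarely state it), harmonic
vibrations, and $S_\mathrm{elec} = R\ln(\text{multiplicity})$ for
open-shell species. `ThermoResult` exposes every term so a free energy
can be audited line by line, and the identity
`gibbs_correction = zpe + u_trans + u_rot + u_vib + RT − T·ΣS` holds
exactly by construction.

Internally all energies are J mol⁻¹. Species files may use Hartree,
kJ/mol, kcal/mol or J/mol; tags are converted on read
(1 Hartree = 2625.4996394799 kJ/mol) and restored on write, which keeps
thermodynamic cycles free of silent unit mixing.

### Low-frequency corrections

Continuum-solvent optimizations of hydrogen-bonded clusters produce
soft intermolecular modes whose harmonic entropy diverges as
$\nu \to 0$. Three treatments are provided:

* **C0** — plain RRHO. Reference behaviour; entropy diverges for soft
  modes.
* **C1** — every frequency below $\nu_0 = 100\ \mathrm{cm^{-1}}$ is
  raised to $\nu_0$ before evaluating the vibrational entropy and
  thermal energy. The per-mode entropy is thereby bounded by its value
  at $\nu_0$ (14.45 J mol⁻¹ K⁻¹ at 298.15 K).
* **C2** — each mode's entropy is interpolated between the harmonic
  oscillator and a free rotor of effective moment
  $\mu = h / (8\pi^2 c \nu)$ (reduced against an averaged molecular
  moment $B_\mathrm{av} = 10^{-44}\ \mathrm{kg\,m^2}$), with weight
  $w = 1/(1 + (\nu_0/\nu)^4)$.

Design choices we had to make because the protocol literature leaves
them open:

* Under C1, raising applies to the vibrational **entropy and thermal
  energy** but never to the ZPE — raising ZPE frequencies would shift
  deprotonation energetics nonphysically. A flag
  (`c1_raise_thermal = FALSE`) restricts raising to the entropy for
  comparison.
* Under C2, only the entropy is interpolated; the thermal energy keeps
  the harmonic form, matching the original scope of the interpolation
  scheme.
* The ZPE scale factor defaults to 1.0 and is an explicit knob
  (`zpe_scale`), since protocols cite scale factors without printing
  them.
* The equations are implemented literally in the 1 atm gas standard
  state; an optional `R·T·ln(24.46)` per-species correction to the
  1 mol/L state exists but defaults off, because the adopted proton
  free energy constant already absorbs state conventions.

A subtlety of the C2 interpolation worth knowing: at high frequency the
weight tends to 1 (at 3000 cm⁻¹, $w = 1 - 1.2\times10^{-6}$) and the
deviation from the harmonic entropy is absolutely negligible
(below $10^{-5}$ J mol⁻¹ K⁻¹), but since the harmonic entropy itself
tends to zero there, *relative* agreement is not a meaningful way to
state this limit; our tests assert the absolute one. At 10 cm⁻¹ the
result is within $10^{-4}$ relative of the pure free-rotor entropy.

## From free energies to pKa

$$\mathrm{p}K_a = \frac{\Delta G_\mathrm{deprot}(\mathrm{sol})}{2.303\,R\,T}$$

with the printed literals $R = 8.314$ J mol⁻¹ K⁻¹ and 2.303 (selectable
as $\ln 10$; the difference is below 0.02%) — the thermochemistry itself
uses CODATA $R = k_B N_A$. The direct route subtracts solution-phase
free energies and adds the experimental aqueous proton free energy
$\Delta G_{H^+}(\mathrm{sol}) = -1131.44$ kJ mol⁻¹ (a 298 K value; the
temperature is configurable but that constant is not
temperature-corrected). The indirect route goes through the gas phase
and per-protocol solvation energies; the two are algebraically
identical for consistent inputs, and the package enforces that identity
in its tests to float precision.

Conjugate pairs are validated structurally: the base must carry one
charge less than the acid, and both sides must have the same
explicit-water count — all supported cycles are water-balanced. An
override (`allow_water_imbalance`) adds $n \cdot G(\mathrm{H_2O})$
terms from a user-supplied water record, since an unbalanced cycle is
otherwise undefined.

Protocols P1–P6 are metadata and validators: `resolve_protocol_method()`
returns the method label a protocol prescribes (by charge class, radical
character, the sulfonate special case routed to the anion method, and
the heavy-atom basis annotation for iodine), and the explicit-water
protocols P4–P6 refuse bare-solute species. The package never launches a
calculation from these labels.

## The benchmark module

The embedded experimental table holds the ten para-substituents
(H, C₄H₉, CF₃, CH₃, OCH₃, CN, COCH₃, I, NH₂, SO₃⁻) for both systems:
one literature value per radical cation and one to three per anilinium
(18 anilinium values in total). Values are averaged per compound
whenever two or more exist — the footnoted convention says "more than
two", but two-value compounds are plainly meant to be averaged too, and
the raw lists are retained either way. `benchmark_run()` matches
calculated values to the table, reports per-compound
$\Delta\mathrm{p}K_a = |{\rm calc} - {\rm exp}|$, the RMSE
$\sqrt{\sum (\mathrm{calc}_i - \mathrm{exp}_i)^2 / n}$, and an OLS
regression with calculated values on the y-axis. `rmse_aggregate()`
summarizes RMSE across method combinations as mean ± SD; the SD uses
the sample (n−1) denominator by default with a population option, since
the convention is unstated in the protocol literature.

The headline RMSE values of the original benchmark (0.563, 0.384,
0.310, 0.349 for the CBS-QB3 / M062X combinations) require the authors'
quantum-chemistry outputs, which are not public; reproducing them is
explicitly out of scope. What the package reproduces is the machinery:
given the same inputs, it computes the same statistics.

## Synthetic fixtures: what they do and do not show

`generate_species()` draws random non-colinear geometries (elements
from C/N/O/H, coordinates uniform in ±2 Å), positive frequencies with a
prescribed number of soft modes below 100 cm⁻¹, and electronic energies
uniform in −10 to −2 Hartree — the scale of the few-atom synthetic
molecules it builds. `generate_pair_with_known_pka()` then back-solves
the base's electronic energy (the single linear unknown in the cycle)
so the full pipeline returns an exact target pKa, and attaches a
consistent indirect decomposition (random solvation energies in −40 to
−10 kJ mol⁻¹, gas free energy defined by difference). Everything is
deterministic per seed, and generation never disturbs the caller's RNG
stream.

These fixtures exercise every formula, unit conversion and bookkeeping
path end to end with machine-precision ground truth. They are not
anilines: frequencies are not from a force field, geometries are not
minima, and passing tests say nothing about the accuracy of any
electronic-structure method on real molecules — that is what the
experimental benchmark table is for.

Problem sizes used in the shipped tests and acceptance script: 100-pair
sweeps for the cycle identity and parameter recovery (3-atom species,
all three schemes), and a 10⁴-compound synthetic set for checking that
realized noise RMSE converges to the injected σ. The whole suite runs
in well under a minute.

## Numerical choices and degenerate inputs

* Linearity: a molecule is linear when its smallest principal moment is
  below $10^{-6}$ times the largest; single atoms are monatomic with
  zero moments. Stiff-mode formulas use `expm1`/`log1p` so entropies
  underflow cleanly to zero instead of losing precision.
* Imaginary frequencies are an error by default (all benchmark species
  are optimized minima); `allow_imaginary = "drop"` removes them with a
  warning.
* Frequency counts are checked against 3N−6 / 3N−5 / 0 but deviations
  only warn, since constrained or projected frequency sets legitimately
  deviate.
* Eigenvalue noise of the inertia tensor is clipped at
  $10^{-12}$ relative before unit conversion, so exactly linear
  geometries report a clean zero moment.
* The published argon standard entropy (154.846 J mol⁻¹ K⁻¹) is a 1 bar
  value; at 1 atm the Sackur–Tetrode form gives 154.736, and the tests
  distinguish the two standard states.

## Limitations

* No anharmonicity, hindered-rotor scans, isotope effects or
  condensed-phase translational models.
* Single deprotonation site; no microscopic/macroscopic multi-site
  schemes or proton-exchange reference acids.
* The proton solvation constant is a fixed 298 K number; computing at
  other temperatures is allowed but that constant is not adjusted.
* No parsing of native quantum-chemistry logs: species records are
  JSON (schema in `inst/extdata/species-record-schema.json`), and any
  third-party parser can populate them.
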