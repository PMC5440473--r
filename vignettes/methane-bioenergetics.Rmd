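---
title: "Methods: catabolic energy densities for methane cycling in serpentinizing fluids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: catabolic energy densities for methane cycling in serpentinizing fluids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serpenergy)
```

## The model

`serpenergy` estimates how much chemical energy five methane-cycling
catabolisms can deliver per liter of a measured fluid. The chain is:

1. **Fixed-pH equilibrium speciation.** The measured pH is taken as a fact
   about the fluid, not something to re-solve: `a(H+) = 10^-pH` throughout.
   The carbonate, ammonium and phosphate systems are partitioned among
   their protonation states by mass-action at the in-situ temperature,
   using equilibrium constants derived from the same formation-energy table
   that powers the reaction energetics (`ln K = -ΔG°rxn(T)/(RT)`), so there
   is a single thermodynamic basis with no internally inconsistent
   "textbook pK" shortcuts. Activity coefficients come from the Davies
   equation, and the ionic strength is solved self-consistently
   (coefficients depend on I, I depends on the speciated molalities) by
   fixed-point iteration to a relative tolerance of 1e-10.

2. **In-situ Gibbs energy.** For each reaction,
   `ΔG = ΔG°(T) + R T ln Q`, with `ΔG°(T)` from the stoichiometric sum of
   25 °C formation energies plus a Gibbs–Helmholtz (constant-ΔH°)
   temperature correction, and `ln Q = Σ ν ln a` over the speciated
   activities, with `a(H2O) = 1` and `a(H+) = 10^-pH`.

3. **Energy density.** The reactant whose measured (or scenario-assumed)
   total is scarcest per stoichiometric unit caps the reaction extent:
   `extent = min(c_i / |ν_i|)` in µmol per liter. The yield is
   `energy (J/L) = max(0, -ΔG) × extent / 1000`; endergonic reactions are
   clamped to zero because the quantity of interest is *available* energy.

The reaction catalog covers hydrogenotrophic methanogenesis
(CO₂(aq) + 4 H₂(aq) → CH₄(aq) + 2 H₂O), acetoclastic methanogenesis
(CH₃COO⁻ + H₂O → CH₄(aq) + HCO₃⁻), anaerobic methane oxidation coupled to
sulfate (→ HCO₃⁻ + HS⁻ + H₂O) or nitrate with nitrite as the reduced
product (CH₄ + 4 NO₃⁻ → HCO₃⁻ + 4 NO₂⁻ + H⁺ + H₂O), and aerobic methane
oxidation (CH₄ + 2 O₂ → HCO₃⁻ + H⁺ + H₂O). Bicarbonate is the
inorganic-carbon product of the oxidations because it dominates dissolved
inorganic carbon at circumneutral-to-alkaline pH; methanogenesis consumes
dissolved CO₂ explicitly. All five ship in an editable CSV
(`inst/extdata/reaction_catalog.csv`), so an alternative electron-acceptor
product (say N₂ instead of NO₂⁻ for nitrate-AOM) is a one-line data edit,
not a code change. Every catalog entry must pass element and charge
balance at load time.

## Parameters that matter

| Parameter | Default | Units | Why this value |
|---|---|---|---|
| `filler_na_cl_mM` | 12.5 | mmol/L | Nominal Na⁺ = Cl⁻ standing in for the measured salinity of dilute serpentinizing fluids (conductivity ≲ 700 µS/cm); midpoint of the 10–15 mM customarily used for charge balance in such systems. It affects only the ionic strength. |
| `o2_fraction_air_sat` | 0.001 / 0.01 | — | Dissolved O₂ was not measured; the scenario brackets 0.1 % and 1 % of air-saturation solubility (258 µM at 25 °C, interpolated 20–35 °C from an embedded freshwater table). |
| `acetate_fraction_doc` | 0.01 / 0.10 | — | Acetate was not measured; bracketed as 1 % and 10 % of DOC. Default **carbon basis**: acetate (µM) = fraction × DOC/2, two carbons per acetate, because DOC is a carbon-atom inventory. A `molar` basis (fraction × DOC) is selectable for comparison with analyses that read the fraction as molar. |
| `assumed_so4_uM` | `NA` | µmol/L | Sulfate was not measured. Sulfate-AOM cells are reported as *skipped with a reason* unless the analyst supplies a value — the package never silently invents a measurement. |
| `trace_product_uM` | 0.05 | µmol/L | Product species whose measured total is zero (NO₂⁻ at the springs) or absent (HS⁻) would make `ln Q` undefined. They receive this nominal trace concentration — half the reporting resolution of the packaged field table — and are flagged `assumed` in the speciation output. Because the affected term enters as `4 RT ln a(NO₂⁻)` against a ΔG° near −475 kJ/mol, moving the trace anywhere in 0.001–1 µM shifts ΔG by tens of kJ/mol without approaching zero; no ordering in the packaged analysis depends on the choice. |
| Davies slope `A(T)` | 0.4883 + 8.074e-4·t(°C) | — | 0.509 at 25 °C; the Davies model is adequate to I ≈ 0.5 molal and these fluids sit near I ≈ 0.015. A B-dot implementation would differ in the third decimal of log γ here. |

Other fixed conventions: neutral dissolved species (CH₄, H₂, O₂, CO₂, NH₃)
carry unit activity coefficients (no salting-out — negligible at this ionic
strength); molality is taken equal to molarity (density ≈ 1 kg/L);
`a(H2O) = 1`; nitrate is derived as `max(NOx − NO₂, 0)`; the gas constant
is 8.314 J/(mol·K); pressure corrections are out of scope (1 bar).

**Limiting totals are bulk totals**, not speciated sub-pools: the extent of
hydrogenotrophic methanogenesis is capped by total DIC and total dissolved
H₂, not by the (at pH 11.5, vanishing) CO₂(aq) sub-pool. The rationale is
that the reservoir available to an organism over the residence time of a
liter of fluid is the total pool, which re-equilibrates as CO₂(aq) is
drawn down; the in-situ ΔG, by contrast, is evaluated at the actual
speciated activities. This asymmetry is deliberate and follows the
standard practice for energy-density estimates in hydrothermal systems.

## Thermodynamic data

The embedded species table (`inst/extdata/thermo_species.csv`) carries
ΔG°f and ΔH°f at 25 °C / 1 bar for 22 aqueous species, transcribed from the
standard SUPCRT-consistent compilations (Shock & Helgeson's aqueous-ion and
organic-solute tables; CODATA water), with the source noted per entry.
Over the 24–30 °C span of these fluids, the constant-ΔH° van 't Hoff
correction deviates from a full revised-HKF evaluation by well under
1 kJ/mol, which is far below the spread induced by the scenario
assumptions; reimplementing the HKF equation of state would add complexity
without changing any conclusion. The valid window is enforced as
283–333 K.

Self-consistency is tested rather than assumed: the dissociation constants
derived from the table reproduce pKw ≈ 14.0, pK1 ≈ 6.34, pK2 ≈ 10.33 at
25 °C, the ΔG = ΔG° + RT ln Q identity is exact by construction, and
forward/reverse reactions are antisymmetric to rounding.

## Numerical choices and degenerate inputs

- The ionic-strength fixed point is a strong contraction here (γ feeds
  back only weakly into the partitioning); it converges in < 10 iterations
  on every fixture and errors after 100.
- An independent oracle (`speciation_oracle`) solves the same equations by
  closed-form ionization fractions plus a bracketing grid search and
  `uniroot` on `I_implied(I) − I` — no fixed-point iteration — and agrees
  with the solver to ~1e-11 relative on random fluids; the tested
  contract is 1e-6.
- `known_speciation_case` constructs fixtures whose self-consistent ionic
  strength is *exactly* the requested value by solving the Na/Cl filler in
  closed form (including the two trace-product ions), so solver recovery
  can be asserted at 1e-6 without tolerance games. The pure-water variant
  (I → 0) cannot cancel its own-ion ionic strength (~1e-7); there the
  γ-free activities (H⁺, OH⁻, CO₂) remain exact.
- Below-detection cells are `NA`, excluded from summaries, never imputed.
  Zero totals speciate to zero molality; a zero *reactant* total yields a
  zero extent (zero energy), while a zero *product* total triggers the
  trace convention above.
- Ties in the limiting-reactant argmin resolve to catalog order, as do
  all-zero energy rankings.
- With the embedded table, pKw at 25 °C is 13.995, so a pH 7.00 fluid at
  25 °C has a(OH⁻) = 1.01e-7 — "neutral" to within the accuracy of the
  formation energies, and the tests assert exactly that rather than a
  fictitious pKw of 14.000.

## What the synthetic data emulate — and what they do not

`simulate_fluid_table` draws spring and background endmembers with the
contrasts that define the study system: springs at pH 11.5 ± 0.1,
ORP ≈ −300 mV, CH₄ lognormal about 500 µM, H₂ about 30 µM, DIC about
200 µM; background at pH 8.2 ± 0.4, oxidizing, CH₄ about 0.3 µM, DIC about
550 µM. Concentrations use lognormal noise (positive, order-of-magnitude
spreads), pH/temperature/ORP normal noise; the chosen coefficients of
variation reproduce the observed ranges (e.g. spring CH₄ spanning roughly
150–900 µM). `simulate_taxonomy_table` allocates a fixed read depth by a
single multinomial draw over representative guild lineages and filler taxa,
with default spring-like communities spanning combined methanogen + ANME
fractions of 0.40–0.90 of archaeal reads.

These generators are distributional emulators, not process models: there is
no mixing, titration or reaction-path chemistry behind the fluid draws, no
correlation structure between analytes beyond the endmember means, and the
taxonomy tables contain none of the chimeras, misclassifications, or
compositional artifacts of real amplicon data. Tests passing on synthetic
data therefore demonstrate that the *computational machinery* recovers
known ground truth — not that the field data satisfy the generators'
assumptions. One global integer seed controls every draw; sub-stages derive
seeds by fixed offsets, so each stage is independently reproducible.

Problem sizes used by the packaged analyses and checks: 100 random fluids
for the solver-vs-oracle comparison, 1,000 replicate communities at 10,000
reads for guild-fraction recovery (4σ multinomial band, ≥ 95 % coverage
asserted), 200-site tables for law-of-large-numbers checks.

## Design decisions that were genuinely open

- **Fixed-pH speciation, no charge-balance solve for H⁺.** The pH was
  measured in the field; re-solving it from an incomplete analyte list
  would degrade a good measurement with a poor closure assumption. The
  Na/Cl filler exists only to represent salinity in the ionic strength.
- **Carbon-basis acetate.** "Acetate as a fraction of DOC" is ambiguous;
  DOC is measured in carbon atoms, so the default divides by two. The
  molar reading is one flag away, and the bracketing scenarios (1 %/10 %)
  dwarf the factor-of-two ambiguity anyway.
- **Skip-not-guess sulfate.** An assumed sulfate would silently dominate
  the AOM comparison; the grid instead carries an explicit skipped cell
  until the analyst commits to a value.
- **Rank-aware guild matching.** Methanogen orders match at the order
  rank, methanotroph genera at the genus rank, ANME labels anywhere —
  protecting against coincidental name reuse across ranks. The guild lists
  keep the historical misspelling "Methyothermus" *and* the standard
  "Methylothermus"; Methanoperedens (ANME-2d) overrides its
  Methanosarcinales parentage into the ANME guild, and per-sample
  denominators are per-domain read totals (archaeal fractions over
  archaeal reads).

## Known limitations

- The energy-density orderings among pathways can hinge on the scenario
  assumptions. On the packaged fixture, nitrate-AOM falls below both
  methanogenesis pathways at Springs 8 and 9 under the 10 %-acetate
  scenario, but at Q. Danta — where DOC is only 5.6 µM — nitrate-AOM
  (≈ 0.12 J/L) exceeds the acetoclastic yields, and under the 1 %-acetate
  scenario it exceeds them at all three springs. `analysis/03_energetics.R`
  prints this sensitivity note alongside the rankings; consumers of the
  orderings should treat "AOM below methanogenesis" as robust only where
  the margin survives the scenario bracket.
- Measured ORP is carried as data but does not enter the speciation; no
  redox pairs are equilibrated against it.
- No mineral saturation indices, degassing kinetics, Pitzer/B-dot activity
  models, pressure corrections, growth yields, or kinetic rate laws.
- The fixture carries site-averaged values; replicate-level spread is not
  represented.
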