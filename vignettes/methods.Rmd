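---
title: "Methods: single-cell SIP rates, quotas and biomass yields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell SIP rates, quotas and biomass yields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
library(nitrisip)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, and the choices made where the design was genuinely
open. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The measurement chain

Single-cell stable isotope probing of nitrifiers couples three measurements
taken on the same seawater incubations:

1. **Bulk tracer time series.** ¹⁵N-labeled substrate (ammonium, urea,
   cyanate or nitrite; 5 µM additions) is added to triplicate serum bottles;
   the ¹⁵N-product pool is sampled at 0, 6, 12 and 24 h.
2. **nanoSIMS ion counts.** At 24 h, cells are filtered, identified by
   CARD-FISH, and rastered plane by plane; each region of interest yields
   per-plane counts of ¹⁵N- and ¹⁴N-bearing (and ¹³C/¹²C) secondary ions.
3. **Cell counts.** Microscopy abundances of each population before and
   after the incubation.

Everything downstream — per-cell rates, quotas, energy fluxes, yields — is
arithmetic on these three tables plus a small set of constants.

## Isotope arithmetic and the counting-error filter

The atom fraction `x = minor/(minor+major)` is computed on counts summed
over all acquisition planes, and the atom-percent excess subtracts the
natural-abundance baseline: 0.37 at% for ¹⁵N, 1.11 at% for ¹³C
(`natural_abundance()`, overridable). Negative excess values are **kept and
flagged**, never clipped: clipping at zero would bias upward the mean excess
of weakly labeled populations, which matters for the group comparisons.

The per-cell quality filter is the Poisson relative error of the isotope
ratio on plane-summed counts, `sqrt(1/Σminor + 1/Σmajor)`, with cells
retained below 5%. Two choices here were open:

* *Which error formula.* We use the standard counting-statistics propagation
  for a ratio of two Poisson totals. It is monotone non-increasing as planes
  are added (a property test enforces this).
* *Error of the ratio or of the excess.* The threshold is asserted on the
  **ratio's** relative error. Putting it on the excess would make the filter
  blow up at enrichments near zero and would couple the filter to the
  baseline constant; the ratio form depends only on the measurement itself.

The labeling excess of a substrate pool after tracer addition is the
mass-balance value
`100·(purity·added + baseline·ambient)/(added+ambient) − 100·baseline`,
with tracer purity defaulting to 0.99 (configurable; instrument suppliers
rarely exceed 98–99 at%). Because laboratories measure the t₀ labeling
rather than trusting the amendment arithmetic, a directly measured excess
can be attached to the `labeling_state` and takes precedence by default.

## Bulk rates

Rates are the slope of one pooled OLS regression of ¹⁵N-product
concentration on time across **all** points of **all** replicates — not a
mean of per-replicate slopes. A single common slope and intercept is exactly
what "slope across all time points of the triplicates" means operationally,
and a free intercept absorbs abiotic carryover at t₀. Detection is a
one-sided t test of H₀: slope ≤ 0 at α = 0.05; non-significant rates are
retained with `detected = FALSE` rather than dropped, so downstream
summaries choose their own censoring. The labeling correction divides the
slope by `label_excess/100` — exact inverse scaling, verified by parameter
recovery (bias < 2% over 1000 simulated incubations in the acceptance
suite). The 20 ml sampled and replaced at each timepoint is ignored:
concentrations are intensive and the replacement is He/sterile water.

## Single-cell rates

N-assimilation per cell is the cell's attained fraction of the pool labeling
times its nitrogen quota per unit time:

```
rate [fg-N cell⁻¹ d⁻¹] = (at%excess_cell / at%excess_label) · fgN_cell / t
rate [fmol-N cell⁻¹ d⁻¹] = rate_fg / 14
```

Growth rates use the same labeled fraction `f`: the **linear** form
`GR = f/t` is the default because combined multi-substrate growth rates are
reported as sums of per-substrate values, and only the linear form is
additive; the exponential form `−ln(1−f)/t` is available for sensitivity
analysis (it errors at `f ≥ 1`). C-assimilation is inferred from
N-assimilation via Redfield C:N = 6.625 because direct ¹³C enrichment of
small cells on polycarbonate filters is diluted by filter-derived ¹²C at the
cell boundary; no dilution correction is applied by default (a multiplicative
hook exists, default 1.0) — the rates are therefore conservative.

Quotas come in two modes: `per_cell` derives each cell's quota from its own
ROI area, while `population` applies one mean quota to every cell, which is
the mode that reproduces population-level arithmetic. Cells with negative
excess contribute zero rate but stay in the tables for group statistics.

Printed per-substrate assimilation rates and growth rates in this kind of
study are generally *not* mutually consistent under any single quota value
(population averaging of per-cell quotas does not commute with the rate
arithmetic); the package implements the equations as defined and does not
force agreement.

## Morphology and quotas

NOB cells are capsules (cylinder + two half-spheres), AOA are prolate
spheroids. ROI areas are treated as mid-plane projections — rectangle plus
circle for the capsule, ellipse for the spheroid — and inverted at an
assumed aspect ratio (default 1.5 for AOA, matching 0.6 × 0.4 µm cells; 3
for the rod-shaped NOB, not printed anywhere and therefore configurable).
An area-equivalent sphere would be wrong for rods by a factor that grows
with aspect ratio.

Carbon follows the biovolume allometry `C = a·V^b`. The coefficients are not
restated in the source literature at the precision needed, so the defaults
`a = 196 fg, b = 0.486` are **solved exactly** from the two published
anchor pairs (0.06 µm³, 50 fg) and (0.25 µm³, 100 fg); both are
config-overridable. Nitrogen applies C:N = 6.625 directly to the femtogram
amounts (the field convention); the measured *Nitrospina gracilis* ratio
5.9 ± 1.2 can be substituted but is not the default.

## Population bookkeeping

`GR = ln(Nt/N0)/t` and `DT = ln2/GR`; per-cell rates divide the bulk rate by
the **mean** of start and end abundances (the mediating population over the
incubation). Counting error on microscopy abundances is modeled as Poisson
on the cells actually counted and propagated to GR by the delta method —
the source studies report no count errors, but honest synthetic tests need
an error model. Unit conversions (14 fg/fmol N, 12 fg/fmol C, 10⁶ fmol/nmol)
live in one exported constant list and are asserted in tests.

## Energetics

`ΔG = Σν·ΔGf° + R·T·ln Q`, activities equal to molar concentrations
(coefficients of 1), water at unit activity, H⁺ from pH. The shipped
formation-energy table uses standard aqueous values (NO₂⁻ −32.2, NO₃⁻
−111.3, NH₄⁺ −79.31 kJ/mol) **with O₂ at its gas-reference value of 0**
while its dissolved concentration (63 µM default) enters the quotient. This
convention is deliberate: it reproduces the ≈ −65 kJ/mol found for nitrite
oxidation under the default in situ conditions (nitrite 848 nM, nitrate
2250 nM, 28 °C), whereas an aqueous-state ΔGf°(O₂) ≈ +16.4 kJ/mol shifts
every oxygenase reaction by −8.2 kJ per half-mole of O₂. The table is fully
overridable per reaction. Temperature correction of ΔGf° over the 3 K
between standard state and 28 °C is far below the ±5 kJ/mol tolerance used
anywhere and is not applied. Ammonia oxidation defaults to NH₄⁺ as written
substrate (with a speciation toggle to NH₃); published in situ values near
−262 kJ/mol depend on supplementary conditions that are not reproducible
from main-text data, so downstream flux/yield computations take ΔG as an
*input* (−65/−262 defaults in the reference scenario) and
`gibbs_free_energy()` is validated against an independent analytic oracle,
with the nitrite value as the single external cross-check.

Energy flux is `rate · |ΔG| · 10⁻⁶` (J L⁻¹ d⁻¹) and biomass yield is
C-assimilation divided by flux (nmol-C J⁻¹) — invariant under simultaneous
rescaling of both rates, which a test asserts.

## The synthetic world

The generators state one world and keep it:

* Incubations: triplicates at 0/6/12/24 h, 5 µM additions to ambient pools
  (ammonium 320 nM, nitrite 848 nM, urea 69 nM, cyanate 11.5 nM), linear
  product accumulation, **Gaussian noise σ = 10 nmol/L** on concentrations.
  σ is not stated in the source material; 10 nmol/L is a realistic
  GC-IRMS-scale uncertainty relative to the tens-to-hundreds of nmol/L
  signals involved, and it was fixed once, before any test outcome.
* nanoSIMS: 40 planes, Poisson ion counts with per-plane intensity ∝ ROI
  area (lognormal areas, CV 0.2), linear label accumulation
  `x* = x_nat + GR·t·(label/100)` — consistent with the linear growth model.
* Counts: exponential growth, Poisson counting at ~500 counted cells per
  census.

What a green recovery test establishes: the estimators are unbiased and
their spread matches counting statistics *under this stated world*. What it
does not establish: robustness to instrument drift, quasi-simultaneous
arrival effects, dead time, ROI segmentation error, non-Poisson
overdispersion of cell counts, substrate cross-feeding during incubations,
or isotope dilution by CARD-FISH — all of which are upstream of, or outside,
this package's scope.

## Numerical and interface choices

* All tables are header-keyed delimited text with units encoded in column
  names (`rate_nmol_L_d`); column order is irrelevant.
* The configuration file is declarative JSON with nested blocks (`paths`,
  `constants`, `modes`, `thermo`); unknown keys are rejected rather than
  ignored.
* All randomness flows through one base seed; generators save and restore
  the caller's RNG state, and equal seeds produce byte-identical files.
* Degenerate inputs fail loudly: zero total ion counts, single-timepoint
  designs, non-positive labeling excess, unbalanced reactions, and missing
  species concentrations are errors naming the offending quantity.

## Known limitations

* No isotope-pairing correction for consumption of the ¹⁵N-product pool and
  no saturating rate models: rates are linear-regime estimates.
* Activity coefficients are unity; at seawater ionic strength the ΔG error
  is a few kJ/mol, absorbed by the ±5 kJ/mol tolerance.
* The ¹³C route is carried through the data structures but the headline
  C-rates are N-derived by design (filter-dilution bias).
* Field-scale results (depth profiles, cross-station correlations, MAG
  inventories) require the original cruise and sequence archives and are
  outside the desk-scale scope; they are covered only by the property-based
  suite.
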