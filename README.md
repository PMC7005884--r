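# nitrisip

Single-cell stable-isotope-probing (SIP) ecophysiology of marine nitrifiers.

Marine nitrification is carried out by ammonia-oxidizing archaea (AOA) and
nitrite-oxidizing bacteria (NOB, mainly Nitrospinae), yet the AOA outnumber
the NOB roughly ten to one while the two processes stay in balance. Resolving
that puzzle requires per-cell physiology: how fast individual nitrifier cells
assimilate nitrogen and carbon, how much energy their catabolism dissipates,
and how efficiently they turn that energy into biomass. `nitrisip` implements
the full desk-side analysis chain for such studies:

* **Isotope arithmetic** — atom fractions `x = ¹⁵N/(¹⁵N+¹⁴N)` from nanoSIMS
  ion counts, atom-percent excess over natural abundance (0.37 at% ¹⁵N,
  1.11 at% ¹³C), Poisson counting-error filtering (`√(1/N₋ + 1/N₊) < 5%`
  across all acquisition planes of a cell), and labeling bookkeeping for 5 µM
  tracer additions to ambient pools.
* **Bulk rates** — pooled OLS regression of ¹⁵N-product concentration on time
  across triplicate incubations (t = 0, 6, 12, 24 h), one-sided detection
  test (H₀: slope ≤ 0, α = 0.05), labeling correction
  `rate = slope · 24 · 100/at%excess_label`.
* **Single-cell rates** — N-assimilation
  `(at%excess_cell / at%excess_label) · fgN_cell / t` (fg-N cell⁻¹ d⁻¹;
  ÷14 for fmol), per-substrate and combined growth rates `GR = f/t`,
  Redfield C-from-N conversion (×6.625), Wilcoxon group comparisons.
* **Morphology** — capsule and prolate-spheroid biovolumes, projected-area
  inversion, carbon allometry `C = 196 · V^0.486` fg, Redfield N quotas.
* **Population bookkeeping** — `GR = ln(Nt/N0)/t`, `DT = ln2/GR`, per-cell
  rates from bulk rates and mean abundance, population C stocks and
  assimilation fluxes, marker-gene FPKM fractions.
* **Energetics** — `ΔG = Σν·ΔGf° + RT·ln Q` under in situ conditions,
  catabolic energy flux `rate · |ΔG|` (J L⁻¹ d⁻¹), biomass yield
  (nmol-C J⁻¹).
* **Synthetic data** — seeded generators (Gaussian concentration noise,
  Poisson ion and cell counts) emulating the full measurement structure, so
  every estimator is testable against known ground truth without any
  external data.

## Worked example

The reference scenario (`gom_fixture()`) encodes a hypoxic Gulf-of-Mexico
shelf water column: Nitrospinae at 1.32×10⁷ cells/L (0.25 µm³, 100 fg-C,
bulk nitrite oxidation 564 nmol L⁻¹ d⁻¹, ΔG = −65 kJ mol⁻¹) versus AOA at
4.15×10⁸ cells/L (0.06 µm³, 50 fg-C, ammonia oxidation 2508 nmol L⁻¹ d⁻¹,
ΔG = −262 kJ mol⁻¹).

```r
library(nitrisip)
rep <- run_pipeline(analysis_config(seed = 1))
print(rep)
#> Single-cell SIP analysis report
#>   bulk rates: 2 incubation(s), 0 below detection
#>   cells: 100 measured, 0 failed the Poisson filter
#>   populations: 2
#>   yield table:
#>       taxon energy_flux_J_L_d yield_n_based_nmolC_J yield_measured_nmolC_J
#>  target_NOB          0.036660             2154.9373               463.7207
#>  target_AOA          0.657096              614.8264               105.0075
```

Reading the yield table: nitrite oxidation dissipates only ~0.037 J L⁻¹ d⁻¹
against ~0.66 for ammonia oxidation, yet the NOB fix ~2150 nmol-C per Joule
versus ~615 for the AOA — the nitrite oxidizers are roughly four-fold more
efficient at converting catabolic energy into biomass. The same chain from
the directly measured ¹³C-bicarbonate assimilation gives 464 vs 105
nmol-C J⁻¹. Per-cell oxidation rates come out at 42.7 (NOB) and 6.0 (AOA)
fmol cell⁻¹ d⁻¹:

```r
rep$yield[, c("taxon", "per_cell_rate_fmol_d")]
#>       taxon per_cell_rate_fmol_d
#>  target_NOB            42.727273
#>  target_AOA             6.043373
```

The bulk-rate stage of the same run fit the simulated tracer series back to
their configured truths (564 and 2508 nmol L⁻¹ d⁻¹):

```r
rep$bulk_rates
#>  incubation_id substrate rate_nmol_L_d rate_se_nmol_L_d      p_value detected
#>        nitrite   nitrite      575.9937         6.898280 7.420757e-16     TRUE
#>       ammonium  ammonium     2503.2955         9.811922 1.052408e-20     TRUE
```

## Command line

```sh
BIN=$(Rscript -e 'cat(system.file("scripts/nitrisip", package = "nitrisip"))')
Rscript $BIN simulate --out data --seed 1      # synthetic dataset + truth
Rscript $BIN rates --timeseries data/timeseries.csv --label-excess 84.3
Rscript $BIN quotas --volumes 0.06,0.25
Rscript $BIN report --seed 1 --out results    # full pipeline
```

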