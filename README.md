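# osmoquant

Sulfur-isotope-guided screening and quantification of algal osmolytes in
LC-HRMS data.

Marine microalgae balance external salinity by accumulating small polar
metabolites ("compatible solutes"). Sulfonates such as cysteinolic acid
(2-amino-3-hydroxy-1-propanesulfonic acid, C3H9NO4S) are an
under-characterised part of this osmolyte pool and a growing sulfur
currency in algal–bacterial interactions. osmoquant packages the analysis
side of a discovery-and-quantification workflow for such metabolites in
centroided LC-HRMS runs, aimed at metabolomics practitioners who want a
tested, seedable reference implementation:

* **Exact-mass / isotope engine** — Hill-notation formula parsing,
  monoisotopic and adduct masses (proton-mass convention:
  [M+H]⁺ of C3H9NO4S = 156.03251), and isotope patterns by convolution of
  per-element isotope distributions. A sulfur atom produces the diagnostic
  M+2 companion at Δm = 1.99580 Da with relative abundance
  ³⁴S/³²S ≈ 0.0447.
* **Screening** — XIC extraction (default ±5 ppm ≡ ±0.0005%), feature
  detection, isotopologue envelopes, sulfur flagging via the M+2
  signature, and a differential screen for salinity-up-regulated features
  (fold change ≥ 1.5, Welch p ≤ 0.05).
* **MS/MS annotation** — fragment assignment by neutral-loss combinations
  (H2O, NH3, CO2, SO3, H2SO3) from the protonated precursor.
* **Quantification** — through-origin external calibration with ICH
  LOD/LOQ, censoring flags, and unit conversions
  µM → fmol/cell → intracellular mM (fmol/pL ≡ mM), plus geometric cell
  volumes.
* **Statistics** — fold changes, one-way ANOVA, Tukey HSD with the
  `*`/`**` labelling convention, and survey tables with the usual
  `+` (below LOQ) / `−` (absent) conventions.
* **Synthetic data** — a seeded LC-HRMS simulator (Gaussian peaks, full
  isotope envelopes, log-normal technical noise, Poisson baseline,
  biological CV) and packaged culture scenarios, so every stage can be
  validated against known ground truth.

Everything is data-frame-in / tibble-out and pipe-friendly; fitted
calibrations support `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(osmoquant)

monoisotopic_mass("C3H9NO4S")
#> [1] 155.0252

annotate_fragments(c(156.03232, 138.02196, 56.04979), "C3H9NO4S")
#>          mz      loss fragment_formula theoretical_mz error_ppm
#> 1 156.03232                  C3H10NO4S      156.03251     -1.19
#> 2 138.02196       H2O         C3H8NO3S      138.02194      0.14
#> 3  56.04979 H2O+H2SO3            C3H6N       56.04948      5.61

cfg <- pipeline_config(scenario = "tw_xenic")
res <- run_pipeline(cfg, seed = 1)
res$summary
#>     condition mean_fmol_per_cell sd_fmol_per_cell mean_mm  sd_mm n
#> 1      35 PSU              21.80           0.6986   7.821 0.2506 3
#> 2      50 PSU              54.70           5.6060  19.623 2.0111 3
#> 3 50 PSU 24 h              45.87           7.7923  16.456 2.7954 3
res$comparisons$comparisons[, c("group2", "fold_change", "p_adj", "significance")]
#>        group2 fold_change     p_adj significance
#> 1      50 PSU       2.509 0.0008541           **
#> 2 50 PSU 24 h       2.104 0.0043796           **
```

The fragment table reads: the survey-scan precursor matches the calculated
protonated ion within 1.2 ppm; the 138.022 fragment is the water loss; the
56.050 fragment is the combined loss of water and the sulfonic group
(H2O + H2SO3), leaving the C3H6N⁺ iminium ion. The pipeline summary shows
the simulated xenic diatom experiment: per-cell cysteinolic acid rises
from ~22 fmol/cell at 35 PSU to ~46 (24 h) and ~55 fmol/cell (two
generations at 50 PSU), i.e. roughly 2- and 2.5-fold, both Tukey `**` —
one seed's rendering of the encoded 2.0×/2.4× truth under 10% biological
CV.

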