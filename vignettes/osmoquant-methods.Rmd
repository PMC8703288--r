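---
title: "Methods: sulfur-isotope-guided osmolyte screening and quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sulfur-isotope-guided osmolyte screening and quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmoquant)
```

## Scope and model

osmoquant implements a targeted-metabolomics workflow for sulfonate
osmolytes in microalgae, organised around cysteinolic acid
(2-amino-3-hydroxy-1-propanesulfonic acid, C3H9NO4S), a compatible solute
that marine phytoplankton accumulate under salinity stress. The workflow
has five stages:

1. **Exact-mass and isotope engine.** Monoisotopic masses are element-wise
   sums over an embedded IUPAC/NIST atomic-mass table. The protonated
   adduct adds the proton mass (1.0072765 Da), not the hydrogen atom mass,
   so cation m/z values are electron-mass corrected; for cysteinolic acid
   this gives [M+H]+ = 156.03251. Isotope patterns are convolutions of the
   per-element isotope distributions.
2. **Feature screening.** Chromatographic features are detected per m/z
   trace, isotopologue envelopes are attached, and sulfur-containing ions
   are flagged by the M+2 companion at a mass shift of 1.99580 Da (the
   34S-32S gap) with relative abundance near 0.0447 per sulfur atom.
   Candidates for salinity-responsive osmolytes are features whose mean
   area rises at least 1.5-fold under elevated salinity with a Welch test
   p at or below 0.05.
3. **MS/MS neutral-loss annotation.** Fragment peaks are explained by
   combinations of losses (H2O, NH3, CO2, SO3, H2SO3) subtracted from the
   protonated precursor, choosing the combination with the smallest ppm
   error inside the tolerance.
4. **Quantification.** XIC areas become concentrations through a
   through-origin calibration curve, then per-cell amounts via
   `conc x dilution x extract volume / cells`, then intracellular
   molarity via `fmol/cell / pL = mM`.
5. **Condition statistics.** Fold changes of per-cell amounts, one-way
   ANOVA and Tukey multiple comparisons with the `*` (p <= 0.05) / `**`
   (p <= 0.01) labelling convention.

## Isotope-pattern grouping

Isotopologue components are merged into centroids when their mass shifts
fall within 0.003 Da, rather than being pooled by integer nucleon number.
This matters for the sulfur screen: pooling the whole M+2 group would
average the 34S component (+1.99580 Da) with the 18O2 and 13C2 components
(+2.0042 and +2.0067 Da) and move the centroid to about +1.997 Da, outside
any realistic matching window for the sulfur signature. At the resolving
power this workflow targets (70,000 at m/z 200), the 34S peak is separated
from the O/C M+2 cluster in measured spectra, so the split representation
is also the physically correct one. The default pruning threshold is 1e-4
relative abundance.

## MS/MS tolerance

The package-wide mass tolerance for survey scans and XICs is 5 ppm,
equivalent to the +/-0.0005% relative window used for extracted ion traces.
Fragment annotation defaults to 10 ppm instead: low-m/z fragment ions in
tandem spectra routinely carry larger calibration errors than survey scans.
The reference spectrum of cysteinolic acid illustrates this: the water-loss
fragment at m/z 138.02196 matches theory (138.02194) within 0.2 ppm, while
the combined water + sulfurous-acid loss observed at m/z 56.04979 sits
5.6 ppm above the exact C3H6N+ mass of 56.04948 — assignable at the MS/MS
default, not at the MS1 window. Note that arithmetic that neglects the
electron mass would place this fragment near 4 ppm instead; the package
keeps the electron-mass-corrected convention throughout because it is the
one that reproduces the printed precursor m/z.

## What the simulator emulates — and what it does not

`simulate_run()` renders each analyte as a Gaussian elution profile
(default sigma 0.05 min) whose every in-peak scan carries the full isotope
envelope, with the amplitude normalised so the monoisotopic XIC area equals
`response_factor x concentration`. Technical noise is multiplicative
log-normal per centroid with unit mean (default CV 2%, a free choice: the
within-run CV of the reference workflow is not reported); baseline noise is
a Poisson number of random centroids per scan (default 2). Runs are 18 min
at one scan per 0.5 s over m/z 75-200, matching the HILIC gradient duration
and acquisition window of the reference method. Biological variability
enters at the experiment level as unit-mean log-normal jitter of the true
per-cell amounts (default CV 10%).

The simulator does **not** emulate profile-mode peak shapes, retention-time
drift or misalignment, ion suppression and matrix effects, tailing (EMG)
peaks, chimeric MS/MS, or mass-axis drift. Passing recovery tests therefore
demonstrates that the analysis chain is self-consistent and unbiased under
the stated noise model — not that it is robust to every artefact of real
LC-HRMS data.

## Packaged scenarios

The salinity scenarios encode the published condition means as true
per-cell amounts, anchored on printed per-cell values:

* xenic *T. weissflogii*: 22.3 fmol/cell at 35 PSU; 2.0x after 24 h at
  50 PSU; 2.4x after two generations at 50 PSU;
* axenic: baseline 1.5x the xenic value; 1.1x (not significant) short-term;
  2.6x long-term;
* *P. minimum*: 50.6 fmol/cell with a 0.7116 pL cell volume, i.e. 71.1 mM;
* *T. weissflogii* cell volume 2.7875 pL, back-derived from its published
  22.3 fmol/cell and 8.0 mM pair.

Values the source material does not state were fixed once at realistic
magnitudes: harvest densities of 1e5 cells/mL (diatom) and 5e4 cells/mL
(dinoflagellate), 30 mL culture filtered, 1 mL methanol extract, 3-fold
injection dilution, N = 3 biological replicates, biological CV 10%,
calibration at 2-100 uM with n = 3, and retention times staggered over
6.5-9.5 min of the gradient with the response factors set to the published
calibration slopes (1.27e7 area/uM for cysteinolic acid). With these
choices the baseline injected concentration (22.3 uM) sits comfortably
above the curve's limit of quantification, as in the reference data.

## Numerical choices and degenerate inputs

* Trapezoidal XIC integration with a linear baseline between window
  endpoints; a +/-4 sigma Gaussian support keeps truncation below 0.01%.
* Through-origin calibration by least squares; residual SD on n-1 degrees
  of freedom; LOD = 3.3 sigma/slope and LOQ = 10 sigma/slope (ICH
  convention, stated explicitly because published LOD:LOQ ratios do not
  pin down a unique convention). Concentrations below LOD/LOQ are flagged,
  never imputed.
* Feature detection estimates each trace's baseline and noise as median
  and MAD; peaks are contiguous segments above baseline + 3 MAD spanning
  at least 5 scans. Envelope members (0.9-4.1 Da above a larger co-eluting
  feature) are marked and excluded from screening, which also suppresses
  genuinely distinct co-eluting ions inside that window — a documented
  limitation, since the screen performs no adduct or envelope
  deconvolution.
* Feature matching across samples is greedy nearest-neighbour within 5 ppm
  and 0.3 min, seeded from the most intense features; no retention
  alignment is attempted.
* The screening Welch test is a discovery heuristic: raw p-values, no
  multiple-testing correction. Constant-area degenerate cases skip the
  test and are flagged.
* ANOVA on all-identical observations returns p = 1 with a warning rather
  than a 0/0 statistic.
* All generators are seeded; a fixed seed gives bit-identical runs,
  experiments and pipeline output files.

## Problem sizes

Validation simulations use N = 3 replicates per condition and average
recovered quantities over 10 independently seeded experiments; at
biological CV 10% this puts the standard error of a recovered fold change
near 3%, small against the 10-15% acceptance windows used in the tests.
Unit tests exercise the same code paths on 4-minute runs to keep the suite
fast.

## Known limitations

Beyond the simulator gaps above: quantification assumes the analyte is
chromatographically resolved at its target m/z (no interference
correction); the sulfur flag assumes singly charged ions and one sulfur
atom by default; the survey formatting reports means and SDs over
biological replicates only. Real-culture concentrations can only be
validated against recovery of configured truths, not against raw archived
spectra.
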