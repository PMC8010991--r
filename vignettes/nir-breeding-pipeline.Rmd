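---
title: "From leaf NIR spectra to breeding decisions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From leaf NIR spectra to breeding decisions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirherit)
```

## The problem

Tree-breeding programs want to rank half-sib families on leaf nutrition
traits — anthocyanin concentration (ANTH), flavonoid concentration (FLAV)
and the nitrogen balance index (NBI, the chlorophyll-to-flavonoid ratio) —
but wet-lab assays for these traits are slow and expensive at trial scale
(thousands of trees). Near-infrared (NIR) reflectance spectra of fresh
leaves can be collected in the field in seconds. `nirherit` implements the
full chain that makes those spectra usable for selection:

1. calibrate a partial least squares regression (PLSR) from the spectra of
   a lab-measured subset of trees;
2. quantify model uncertainty with a repeated random-split protocol and
   choose among spectral pre-treatments and wavelength-selection
   algorithms;
3. predict the traits of the unmeasured trees;
4. estimate variance components, heritability, genetic and phenotypic
   correlations, BLUP family breeding values and realized genetic gain on
   the combined (measured + predicted) trait table, and select families.

Because no public dataset accompanies this kind of field trial, the package
ships a first-class synthetic-data module that generates the whole study:
trial design, genetically structured traits, and trait-linked spectra.
Every downstream stage is tested against it.

## The synthetic trial

`make_design()` lays out the default trial: 50 open-pollinated (half-sib)
families × 5 replications × 6 trees per plot = 1500 trees, of which
`subsample_measured()` marks 500 (stratified by family) as lab-measured.

`simulate_traits()` draws, for trait vector $t$ of tree $i$ in family $f$:
$t_{if} = \mu + a_f + e_{if}$, with $a_f \sim N(0, \Sigma_f)$ shared by the
family and $e_{if} \sim N(0, \Sigma_e)$ per tree. The defaults encode:

* family-variance ratios $q = \sigma^2_f/(\sigma^2_f+\sigma^2_e)$ of
  0.312 / 0.232 / 0.244 for ANTH / FLAV / NBI — back-solved from target
  half-sib heritabilities 0.78 / 0.58 / 0.61 under $h^2 = 2.5\,q$;
* family-level correlations 0.36 (ANTH–FLAV), 0.11 (ANTH–NBI),
  0.09 (FLAV–NBI) and phenotypic correlations 0.16 / 0.09 / 0.12, from
  which the residual covariance is derived;
* means and total SDs (ANTH 0.5 ± 0.20 %, FLAV 0.8 ± 0.18 %,
  NBI 0.4 ± 0.06) chosen so that the validation RMSEs a well-performing
  model attains (≈ 0.10 %, 0.11 %, 0.04 %) are realistic for the printed
  accuracy range of field NIR work. The instrument reports trait
  concentrations as percent mass fraction; NBI is unitless.

Concentrations are kept non-negative by redrawing the residual of an
offending tree (up to 100 attempts) rather than clipping, which would put a
point mass at zero. NBI is simulated directly as a third correlated trait —
this makes its variance components controllable and testable — and the
implied chlorophyll `chl = nbi * flav` is emitted for spectral mixing; the
alternative (simulate chlorophyll, derive NBI) would make NBI's genetic
architecture emergent and untestable.

`simulate_spectra()` builds absorbance as a Beer–Lambert-style additive
mixture: per analyte, Gaussian peaks (ANTH at 2060/2180/2270/2330/2440 nm;
FLAV at 1130/1235/1950/2220 nm; chlorophyll at 1100/1220/1465/1950/2220 nm
— wavelength regions repeatedly reported as informative for these
pigments in leaf NIR work; one sub-1100 nm flavonoid feature was moved
in-grid to 1130 nm) scaled by the tree's concentration, plus a linear
baseline. Each of 3 probe scans applies multiplicative/additive scatter
`(1 + a) A + b` and independent band noise; the stored spectrum is the scan
mean. The grid is 234 bands, 1100–2498 nm in 6 nm steps (the nominal
1100–2500 nm range truncated to a whole number of steps).

Peak amplitudes and the noise level are calibrated once — chlorophyll
dominant (2.4), ANTH 0.40, FLAV 0.12, band noise SD 0.15 — so that a
default run ranks validation accuracy ANTH > FLAV > NBI. That ordering is
structural: ANTH has clean long-wavelength bands; FLAV's bands overlap
chlorophyll's; NBI appears in the spectra only through the
chlorophyll = NBI × FLAV product, so a linear model must approximate a
ratio, and its accuracy is capped by the FLAV accuracy.

What the generator does *not* emulate: radiative-transfer leaf optics,
spatial field autocorrelation, instrument drift, or wet-lab assay error.
Passing tests therefore demonstrate the pipeline's statistical machinery,
not instrument-grade prediction of real leaves.

## Preprocessing

Six pre-treatments are compared: `raw`, `snv`, `d1`, `d2`, `snv_d1`,
`snv_d2`. SNV standardizes each spectrum to mean 0 / SD 1 (sample SD,
denominator n − 1), removing additive offset and multiplicative scatter.
Savitzky–Golay derivatives fit a degree-2 polynomial (the common
chemometrics default; the degree is a parameter) in a 15-point window and
differentiate it at the window center. Design choices:

* derivatives are expressed per nm (divided by the 6 nm step), so values
  are grid-independent;
* edges are trimmed to the interior where the full window fits
  (234 → 220 bands at window 15) rather than padded — padding fabricates
  data exactly where informative ANTH bands (2440 nm) sit near the
  boundary;
* for combined methods SNV runs first, then the derivative (the order the
  method names read in);
* scan averaging happens at simulation time, before preprocessing.

All transforms are row-wise, so they need no fitting and cannot leak
information across the calibration/validation split.

## PLSR and component choice

`fit_plsr()` is a NIPALS PLS1: X and y are mean-centered (not autoscaled —
NIR band variance is informative), components maximize X–y covariance, X is
deflated per component. Cross-validation-heavy loops use an equivalent
crossproduct ("kernel") formulation operating on X'X and X'y with rank-one
downdates per held-out sample (the leave-one-out loop is compiled C++);
tests assert the two paths agree to 1e−8 and match an ordinary
least-squares oracle at full rank.

`loo_select_ncomp()` computes RMSECV for 0..20 components by leave-one-out
and picks the *smallest* k whose RMSECV is within 2 % of the minimum — a
parsimony rule that avoids buying noise-level improvements with extra
components; ties therefore always break toward fewer components. The
chosen counts are emergent quantities and are not pinned by tests.

## Wavelength selection

Four selectors run behind one contract (scores, boolean mask, threshold,
provenance; at least one band is always selected):

* **sMC** — each band is scored by an F-like statistic for its regression
  on the PLSR prediction direction `u = Xb`. The band's own additive
  contribution is removed from the direction before scoring
  (`u₋ⱼ = u − xⱼbⱼ`): without this, every band's chance contribution to
  `u` inflates its own statistic and the F(1, n − 2) cutoff selects ~3×
  the nominal fraction under a global null; with it the null selected
  fraction matches α (0.051 at α = 0.05 over 500 null replicates). A band
  that essentially *is* the model direction falls back to the unadjusted
  projection, preserving power on dominant single-band signals.
* **IPW** (iterative predictor weighting) — band importance
  |coefficient| × SD, normalized to mean 1, multiplies running weights
  over refits until the kept set stabilizes; bands above 10 % of the top
  weight survive.
* **REP** (regularized backward elimination) — repeatedly drops the 10 %
  of bands with the lowest VIP, tracking 10-fold CV RMSE; returns the
  best-scoring set.
* **GA** — a seeded genetic algorithm over 4-band windows
  (population 64, 100 generations, tournament size 2, uniform crossover,
  per-bit mutation 0.01, elitism 1, all-zero chromosomes repaired),
  fitness = −5-fold RMSECV.

All hyperparameters are exposed with those defaults. Selection always runs
inside each calibration split of the evaluation harness, never on the full
data — re-running selection per split is what makes the selection-frequency
maps meaningful and keeps validation leakage-free.

## The repeated-split protocol

`evaluate_pipeline()` draws `n_rep` random 80/20 calibration/validation
splits (unstratified, matching the reference protocol; a family-stratified
option exists). Per split: selector on the calibration half, LOO component
choice on the calibration half, fit, score both halves. The "95 %
confidence intervals" reported for the four statistics are empirical
2.5–97.5 percentile bands over repetitions. Every repetition's seed derives
from the master seed and repetition index by a fixed affine scheme, so any
single repetition is re-runnable in isolation; grid cells share the split
sequence, making comparisons paired. The reference protocol uses 200
repetitions; the end-to-end default configuration runs 50, a desk-scale
choice whose grid ranking is already stable.

`grid_search()` ranks cells by mean validation R², ties by mean validation
RMSE, then by list order (simpler preprocessing first). `run_all()` mirrors
a field study's workflow: preprocessing methods are compared on the full
spectrum first, then selectors are compared on the winning pre-treatment.
`ensemble_predict()` applies all per-repetition models to new spectra and
reports per-tree mean and SD — the error bars carried into the genetics
stage.

## Quantitative genetics

Variance components come from REML fits of
`trait = mean + replication (fixed) + family (random) + residual`
(via lme4; replication is fixed because the trial is a randomized complete
block). Tests pin the estimates to the balanced-design expected-mean-squares
ANOVA closed form. Between-trait covariances use the sum-trait identity
`cov(i,j) = (var(i+j) − var(i) − var(j))/2` on univariate fits — exactly
equivalent to bivariate REML for balanced designs and far simpler.

* Heritability: $h^2 = k\,\sigma^2_f/(\sigma^2_f+\sigma^2_e)$ with
  $k = 2.5$ by default — a deliberate discount of the classical half-sib
  multiplier 4 to guard against part-sib assembly and inbreeding in
  open-pollinated families; $k$ is a parameter and 4 is selectable.
* Genetic correlation: $r_g = \sigma_{f_if_j}/\sqrt{\sigma^2_{f_i}\sigma^2_{f_j}}$.
  The product-form denominator is used because it is the only form under
  which a trait's correlation with itself is exactly 1.
* Phenotypic correlation:
  $r_p = (\sigma_{f_if_j}+\sigma_{e_ie_j})/\sqrt{(\sigma^2_{f_i}+\sigma^2_{e_i})(\sigma^2_{f_j}+\sigma^2_{e_j})}$.
* Standard errors: delete-one-family jackknife — families are the
  independent genetic units, and no analytic SE applies to all three
  statistics at once.
* Breeding values: BLUP shrinkage of family deviations,
  $\mathrm{BV}_f = \sigma^2_f/(\sigma^2_f+\sigma^2_e/n_f)\,(\bar y_f - \bar y)$,
  verified against `lme4::ranef`. Negative variance estimates are truncated
  at zero and flagged.
* Realized gain: mean BV of the top fraction (ranked by that trait's BV)
  minus the mean BV of all families — a gain on the breeding-value scale,
  where the overall mean is ≈ 0; a phenotype-scale gain would add the trait
  mean to both terms and cancel, so the BV scale is reported.
* `select_families()` intersects above-mean rules across traits.

When genetics runs on the combined table (500 lab values + 1000 ensemble
predictions), prediction error attenuates heritability. Independent error
of variance $w(1-R^2)\sigma^2_{tot}$ on the predicted share $w = 2/3$ of
trees forces an attenuation floor of roughly
$h^2\,w(1-R^2)/(1+w(1-R^2))$ — about 0.03 for ANTH, 0.10 for FLAV, and
0.17 for NBI at their achieved accuracies. The test suite checks that the
round-trip estimates never exceed the true-trait estimates on average and
stay within 0.15 of the simulated targets for ANTH and FLAV; for NBI,
whose forced attenuation alone exceeds that band (a structural consequence
of predicting a ratio trait at $R^2 \approx 0.44$), the estimate is
checked against the accuracy-adjusted target $h^2/(1+w(1-R^2))$ computed
from the achieved ensemble accuracy at run time. In practice the observed
attenuation is somewhat smaller than the independent-error floor suggests
because prediction errors are partly family-structured (they mix the
other, genetically correlated traits). That same mixing inflates the
*apparent* genetic correlations among predicted traits — a caveat that
applies equally to any spectra-predicted genetic analysis.

## Numerical and degenerate-input policy

Zero-variance responses, constant spectra, non-PSD covariances, singular
designs (one family) and band-count mismatches raise classed errors
(`nirherit_error_invalid_parameter` / `_schema` / `_degenerate`) naming the
offending sample or cell. Rank-deficient X truncates the component count
with a warning rather than failing. Validation R² may be negative and is
never clamped. Failed repetitions in the harness are recorded with their
reason, never silently dropped.

## Problem sizes used in the checks

The shipped tests run the default 1500-tree trial end to end once
(50 repetitions), the parameter-recovery study at 100 seeded replicates of
the 50 × 30 trial, the sMC null calibration at 500 replicates of
n = 100 × p = 200, and the pipeline heritability round trip over 20 master
seeds at 10 repetitions per trait — sizes at which each check's sampling
error is small relative to its tolerance while the whole suite stays quick
on a single CPU.

## Known limitations

* The spectra generator is an additive peak model, not leaf optics; real
  spectra have water bands, continuum effects and instrument artifacts the
  pipeline would have to contend with.
* PLS1 only (one trait per model); no multi-response PLS2, no
  kernel/sparse/orthogonal PLS variants, and no selectors beyond the four
  implemented (no CARS/UVE/iPLS).
* The genetic model is the balanced half-sib family model: no pedigree or
  genomic relationship matrices, no spatial adjustment, and the bivariate
  shortcuts assume balance (they remain good approximations for mild
  imbalance such as the measured subset).
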