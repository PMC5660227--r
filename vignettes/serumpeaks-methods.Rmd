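---
title: "serumpeaks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{serumpeaks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serumpeaks)
```

# What the package does

`serumpeaks` implements a complete serum MALDI-TOF profiling workflow of
the kind used to discover diagnostic peptide/protein panels for
colorectal cancer (CRC) versus healthy controls (HC):

1. **Spectrum input** — mzXML (CompassXport-style exports) or two-column
   CSV, with a sample manifest carrying group labels and clinical
   covariates. Group assignment only ever comes from the manifest.
2. **Preprocessing** — mass-window restriction, undecimated wavelet
   denoising, top-hat baseline correction, total-ion-current (TIC)
   normalization, in that fixed order.
3. **Peak calling** — per-spectrum local-maximum detection with an SNR
   threshold, then cross-sample clustering along m/z into a
   samples-by-clusters intensity matrix.
4. **Marker ranking** — two-sided Wilcoxon rank-sum tests per cluster,
   per-marker ROC AUC, and a candidate shortlist filter.
5. **Panel selection** — a genetic algorithm (GA) over marker subsets,
   scored by the Youden index of an RBF-SVM under leave-one-out
   cross-validation (LOOCV), followed by a final fit and a blind-set
   evaluation that never refits on test data.
6. **Validation statistics** — empirical ROC with Hanley–McNeil
   confidence intervals and Youden-optimal cutoffs, logistic combination
   of markers, group comparisons, and ROC-derived dichotomization for
   Kaplan–Meier/log-rank survival analysis.
7. **Synthetic cohorts** — a generator with known ground truth so the
   entire pipeline is testable end to end without access to raw sera.

# The preprocessing model

## Undecimated wavelet denoising

Raw linear-mode TOF spectra carry high-frequency detector noise on top
of smooth peaks. We denoise with a **stationary (undecimated) discrete
wavelet transform**: an à-trous filter bank built from the Daubechies
8-tap extremal-phase pair, applied in the Fourier domain with circular
boundary handling. For an orthonormal quadrature-mirror pair the
frequency responses satisfy $|H(\omega)|^2 + |G(\omega)|^2 = 2$, so the
synthesis rule

$$A_{j-1} = \tfrac12\left(\bar H_j A_j + \bar G_j D_j\right)$$

reconstructs perfectly; this identity is unit-tested to machine
precision. The transform is shift-invariant, which avoids the
Gibbs-like artefacts that decimated wavelet denoising produces at peak
flanks.

The noise scale is estimated robustly from the finest detail
coefficients as $\hat\sigma = \mathrm{MAD}/0.6745$ and detail
coefficients are soft-thresholded at the universal (VisuShrink) level
$\hat\sigma\sqrt{2\log n}$ (`threshold_rule = "visu-hard"` switches to
hard thresholding). Defaults: wavelet `d8`, depth
$\min(6, \lfloor\log_2 n\rfloor - 2)$ — standard choices in the
SELDI/MALDI denoising literature; all are configuration keys.

Spectra whose length is a large prime would make the FFT quadratic, so
inputs are reflection-padded to the next 2-3-5-smooth length and
truncated after reconstruction. Consequence: shift-equivariance is exact
in the interior and degrades only within a filter-support distance
(≈ 1000 points at depth 6) of the spectrum ends; the tests assert
interior agreement.

## Baseline correction

The chemical-matrix baseline is estimated by **morphological opening** —
a rolling minimum over `window_da` (default 200 Da) followed by a
rolling maximum over the same window — and then smoothed with a moving
average over `smooth_da` (default 100 Da). A plain smoothed rolling
minimum systematically under-tracks a decaying baseline by roughly its
change across half a window (≈ 3% for a 3000-Da decay constant), while
the opening is *exact* on any baseline that is monotone at the window
scale and never cuts into peaks narrower than the window; this is the
same top-hat construction used by the established MALDI preprocessing
packages. Edges are handled by point-symmetric (odd) reflection, which
keeps the opening exact up to the spectrum ends on monotone baselines.
Negatives after subtraction are clipped to zero, and the step is
idempotent (re-applying changes nothing), both tested.

## Normalization and mass window

TIC normalization rescales each spectrum so its summed intensity equals
a target, by default the cohort-mean TIC; the per-spectrum noise scale
is rescaled identically so downstream SNR thresholds stay meaningful.
Scaling a spectrum by any constant gain leaves the result invariant —
bit-exactly for power-of-two gains, and to one unit in the last place
otherwise (the gain multiplication itself rounds).

The default mass window is 900–10 500 Da, the recorded acquisition
range for linear-mode serum profiling; both bounds are configuration
keys, so a cohort described as spanning a wider range can simply widen
the window rather than the package taking sides on the discrepancy.

# Peak calling

Peaks are strict local maxima with `height / noise_scale >= snr_min`
(default 3). Maxima closer than `min_sep_da` (default 0.3% of m/z, the
typical linear-mode mass accuracy) are pruned keeping the taller one.
Centroids are intensity-weighted means over the apex ± 1 point.

Cross-sample alignment uses single-linkage clustering with centroid
recompute along ascending m/z: a peak starts a new cluster when it lies
farther than `tol_rel` (default 0.003) times the running centroid from
that centroid. Clusters present in fewer than `min_prevalence` (default
0.1) of samples are dropped as singleton noise. Matrix cells hold peak
*height* (not area), matching the single-intensity-per-marker convention
of profiling studies; a sample with several peaks in one cluster
contributes the tallest, and absences are recorded as 0 rather than NA,
which is the convention the downstream rank tests assume. The
clustering is invariant to sample input order because peaks are sorted
canonically first (tested property).

Two practical consequences of these physics-driven defaults are worth
knowing. Planted markers 4 Da apart near 1950 Da fall inside one
cluster (tolerance ≈ 5.8 Da there) and merge into a single differential
feature. And a small peak ~11 Da from a 10-fold larger neighbour (the
2073/2084 Da pair at σ ≈ 4 Da) rides on the big peak's flank; its
local maximum is displaced or absorbed, so it may not be recallable as
a separate cluster. Both effects are visible in the synthetic cohort
exactly as they would be in real data.

# Marker ranking

Each cluster is tested CRC vs HC with the two-sided Wilcoxon rank-sum
test: exact distribution when the smaller group has ≤ 8 samples and
there are no ties, otherwise the normal approximation with tie and
continuity corrections. The per-marker AUC is $U/(n_1 n_2)$ with ties
counted 0.5, oriented ≥ 0.5; direction comes from the group means. No
multiple-testing correction is applied to the ranking — the screening
convention ranks by raw p — but a Benjamini–Hochberg column is emitted
for information. Sorting ties break by larger AUC then lower m/z so
output order is deterministic.

The candidate filter has two presets: the discovery screen
(`p < 0.01`) and the shortlist (`p < 1e-5`, `AUC > 0.78`, top 10).
Whether the AUC bound acts as a hard filter or merely described the
observed candidates is ambiguous in the source protocol; both
thresholds are exposed, and the shortlist preset applies them as
filters.

# Panel selection

The GA works on bit-vector chromosomes over the candidate set with at
most `max_panel_size` bits (over-long chromosomes are repaired by
dropping random bits). Fitness is the LOOCV Youden index
$J = \text{sens} + \text{spec} - 1$; ties prefer fewer members, then
lower summed candidate p-values. Uniform crossover (rate 0.8), per-bit
mutation (0.02), tournament selection and elitism (2) are used, and the
best panel *ever seen* is returned, which makes the best-fitness
trajectory non-decreasing by construction (asserted on every run). The
seed is a mandatory config field. LOOCV results are cached per subset,
so cost scales with distinct subsets visited, not with
population × generations.

Inside every LOOCV fold, features are `log1p`-transformed (profiling
intensities are strongly right-skewed) and z-scored **on the n−1
training samples only**; the held-out sample is standardized with those
fold statistics. The SVM is e1071's RBF machine with C = 1 and
γ = 1/(number of features × feature variance), which after z-scoring
is 1/d; an inner hyperparameter search is deliberately absent so the
LOOCV estimate stays honest and cheap. Zero-variance features within a
fold are dropped for that fold and counted.

`fit_final()` freezes the standardization on the full training matrix
and fits once; `blind_test()` matches panel members to the test matrix
by m/z within the clustering tolerance, applies the frozen scaling, and
only consults labels at scoring time. Train/blind splits are supplied
explicitly by the caller (two manifests with disjoint ids, enforced),
never derived automatically — an automatic split is where leakage
hides.

LOOCV at these sample sizes has a known pessimistic bias (the held-out
sample's class is always the slight minority in its training fold), so
null-data Youden indices centre slightly below zero; the test suite
accounts for this.

# Validation statistics

`roc_analysis()` builds the empirical ROC over midpoints between
consecutive distinct scores (plus sentinels), computes AUC by the
Mann–Whitney statistic — identical to trapezoidal integration of the
empirical curve — and a 95% CI by the Hanley–McNeil formula (chosen to
match the "AUC (95% CI)" reporting convention; a bootstrap is easy to
add but not default). The Youden-optimal cutoff is reported in score
space; when several thresholds tie, the one closest to the median score
is reported, the midpoint of the two closest if equidistant. The
package is unit-agnostic about concentrations: cutoffs are reported in
whatever units the scores came in.

`combine_markers()` fits an additive logistic model (continuous
features z-scored, binary features as-is; CEA should be log-transformed
by the caller, as `run_validation()` does, because it is right-skewed)
and scores by the linear predictor, so a single-feature combination
reproduces that feature's ROC exactly (monotone invariance). Perfect
separation falls back to a small ridge penalty (`glmnet`, λ = 10⁻³)
rather than failing.

Survival: expression is dichotomized at the Youden cutoff of the ROC of
expression against the binary 5-year outcome, orientation chosen so
AUC ≥ 0.5; Kaplan–Meier estimation and the two-group log-rank test are
delegated to the `survival` package (the hand-computed hypergeometric
log-rank table is the test oracle, not the implementation). Cox
modelling is out of scope.

# The synthetic cohort generator

The generator emulates the discovery study's conditions: 90 HC and 127
CRC spectra on a 1-Da grid over 900–10 500 Da (9 601 points — chosen to
keep a full end-to-end run at desk scale), 173 common peak clusters of
which 10 are differential with the documented masses and directions
(1781, 1868, 1694 Da up in CRC; 2084, 1947, 6856, 1951, 2886, 2073,
4478 Da down). Specifics:

- **Cluster masses** are drawn once per cohort (planted masses fixed,
  the rest uniform with a minimum separation); all per-sample and
  per-cluster draws descend from one seed, so a cohort is
  byte-reproducible.
- **Intensities** are log-normal. The published per-marker group means
  imply mean/SD ratios near 1, i.e. strong right skew; a log-normal
  with within-group `sdlog = 0.6` reproduces both the skew and
  single-marker AUCs around 0.85–0.92, the regime in which a shortlist
  filter at AUC > 0.78 behaves as documented. The exact distribution is
  the generator's free choice and is documented as such.
- **Fold change** defaults to 2.5 for every planted marker — the
  conservative lower bound of the observed per-marker ratios (which
  range from ≈ 1.7 to ≈ 17.7) and the regime in which a multi-marker
  panel genuinely outperforms single markers. At much larger fold
  changes single markers become individually perfect and the
  fewer-members tie-break would legitimately collapse the panel to one
  or two peaks. Table-1-like per-marker ratios can be injected through
  the `planted` config field.
- **Peak width** grows linearly with m/z (σ = 0.002·mz), mimicking
  linear-mode TOF resolution.
- **Baseline** is a decaying exponential; **noise** is Gaussian with a
  variance that grows with the local signal (shot-noise-like);
  **per-spectrum gain** is U(0.7, 1.3), included specifically so TIC
  normalization has something to undo.
- **Clinical tables**: MST1 concentrations come from truncated-at-zero
  normals whose *post-truncation* means equal the published group/stage
  summary statistics (the published numbers are sample moments of
  non-negative data, so the location parameter is moment-matched);
  CEA is log-normal with a higher CRC mean calibrated to an AUC near
  0.77; FOBT is Bernoulli with CRC positivity 0.641 and HC positivity
  0 (matching its reported 100% specificity).
- **Survival records**: log-normal expression, exponential event times
  with the hazard multiplied by `hazard_ratio` (default 4) below the
  expression cutoff, and uniform early censoring with probability
  `censor_rate` plus administrative censoring at 120 months.

What the generator does *not* emulate: isotope envelopes, adducts,
matrix clusters, mass-calibration drift between acquisition days, and
instrument-specific noise spectra. Passing the end-to-end tests
therefore demonstrates that the algorithms recover known truth under
realistic statistical structure — not that any particular real cohort
would yield the same panel.

# Reproducibility and numerical choices

- One global seed fans out to per-stage seeds via a fixed counter-based
  derivation (`stage_seed`), all below 2³¹; the same config and seed
  reproduce a discovery report exactly.
- The preprocessing order restrict → denoise → baseline → normalize is
  fixed and recorded step-by-step in each spectrum's `processing_log`.
- Degenerate inputs error loudly and early (all-zero spectra, empty
  mass windows, single-class labels, constant expression, no events),
  rather than producing silent zeros; undefined rates are `NA`, never 0.
- Display rounding follows the prediction-table convention: half-up to
  one decimal, with unrounded values retained in every object.
- End-to-end problem sizes used by the automated checks: the full
  216-sample cohort at a 1-Da grid for the discovery reproduction
  (20 seeds), and 14–48-sample fixtures for the algorithmic oracles;
  these sizes make the whole suite run in minutes on a single core
  while leaving every algorithmic path identical to a full-scale run.

# Known limitations

- mzXML is the only instrument format read natively (mzML/imzML and
  vendor raw formats are out of scope); centroided input effectively
  bypasses the profile-mode preprocessing assumptions and should skip
  to peak clustering.
- Missing cluster intensities are zero-filled; reading the local
  spectrum intensity instead is a documented alternative that the peak
  caller does not currently implement.
- The GA finds good panels, not provably optimal ones; on ≤ 10
  candidates it is verified against exhaustive search, beyond that no
  optimality claim is made.
- Mass recalibration against calibrant peaks, isotope deconvolution and
  probability calibration of the SVM are out of scope.
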