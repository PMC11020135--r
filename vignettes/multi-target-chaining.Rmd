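---
title: "Multi-target sequential chaining: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-target sequential chaining: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

ionochain predicts element concentrations (ppm) in plant tissue from
hyperspectral reflectance spectra. This vignette explains the model and the
procedure the package implements, the parameters that matter, the
numerical and design choices that were genuinely open, and what the
synthetic validation studies do and do not demonstrate.

## The estimation problem

A sample is one region of interest (ROI) — typically half a leaflet —
summarized as a median reflectance spectrum over several hundred narrow
bands between roughly 384 and 2,518 nm, paired with element concentrations
measured destructively (e.g. by ICP-MS). Single-target regression (STR)
fits one model per element on the spectra alone. Elements are, however,
physiologically interdependent, and a spectrum that carries little direct
signal for one element may still predict it indirectly through a related
element. Multi-target sequential chaining (MTSC) exploits this by
augmenting the feature matrix with *predicted* concentrations of other
elements, selected greedily.

## Preprocessing chain

The spectral correction pipeline runs in a fixed, logged order:
**standardize → Grubbs filter → Savitzky–Golay → first derivative**.

* **Standardization** (`standardize_bands()`): each band column is
  z-scored across samples. The scaler is fitted on the training split only
  and applied unchanged to validation/test data. Per-band z-scoring (not
  per-spectrum SNV) is used: "standardizing spectra" most commonly means
  column-wise scaling ahead of chemometric correction. A zero-variance
  band maps to 0 with a warning rather than an error.
* **Outlier removal** (`grubbs_outliers()`): the iterative two-sided
  Grubbs test at α = 0.05, with critical value
  G_crit(n, α) = ((n−1)/√n)·√(t²/(n−2+t²)), t the upper α/(2n) t-quantile
  on n−2 df. Outlier removal must operate on whole samples to keep the
  table rectangular, so the statistic is applied to each sample's **mean
  standardized reflectance** — the least-assumptive per-sample summary.
  Removal happens only when fitting on training data, never at
  test-application time. Alternative per-band modes could be added behind
  the same interface.
* **Savitzky–Golay smoothing** (`savgol_smooth()`): local least-squares
  polynomial smoothing, window 15 nm, degree 3 by default. The nm window
  converts to an odd band count as the odd integer nearest to
  `window_nm / median band spacing` (ties round *down*, keeping the
  smoothing conservative), floored at the smallest odd integer ≥ degree+2.
  Edges use a one-sided polynomial fit on the truncated window, so any
  spectrum polynomial of degree ≤ 3 passes through untouched, edges
  included — the property the test suite asserts.
* **First derivative** (`first_derivative()`): forward difference
  (S(λᵢ₊₁) − S(λᵢ)) / (λᵢ₊₁ − λᵢ), removing additive baseline offsets. The
  output band is labelled by the **left endpoint** λᵢ (midpoint and right
  endpoint would be equally defensible; one had to be fixed) and the
  output has one band fewer.
* **Target scaling** (`minmax_scale()`): element concentrations are
  min–max scaled to [0, 1] with parameters learned on training folds only.
  Test values falling outside the training range map outside [0, 1] and
  are deliberately **not clipped**; every learner must tolerate that.
  Metrics are reported in ppm via the inverse transform.

## Base learners and tuning

Five learners sit behind one fit/predict contract (`fit_learner()`):
PLS (mixOmics), Ridge and Lasso (glmnet), linear-kernel SVM (e1071) and
random forest (ranger, 300 trees, single-threaded, seeded). The customary
tuning *ranges* are materialized as concrete default grids
(`default_grid()`): PLS components 1–20; Ridge/Lasso penalty 10^x with 8
even exponents on [−4, −0.5] (bounds quoted as negative numbers are read as log₁₀ exponents of the
regularization strength); SVM gamma
4 log-spaced points on [10⁻⁴, 0.1] crossed with cost 5 log-spaced points
on [0.1, 1000]; RF crosses feature fraction, depth, node size and bagging
fraction. Grid densities are package defaults chosen to keep a desk-scale
run in minutes, and are overridable per experiment. Gamma is inert for a
truly linear kernel; it is kept in the grid for interface fidelity.

`grid_search()` scores every configuration by mean k-fold out-of-fold R²
(the target scaler refit inside each fold) and breaks ties toward the
simpler model — fewer components, stronger shrinkage, smaller cost,
shallower forest — then grid order. PLS is special-cased: one maximal-rank
fit per fold yields predictions for every component count, and component
counts beyond the data rank are capped rather than failing. Tuning happens
once per (element, learner) on the spectral features alone and is reused
for augmented feature sets; per-iteration re-tuning would multiply cost
with no stated benefit.

## The chaining loop

`fit_mtsc()` maintains the current feature set (bands plus accepted Ê
columns) and iterates:

1. **Candidate features.** For every remaining pool element c, build the
   column Ê_c. This is fold-specific: for outer fold f's validation rows,
   Ê_c comes from a candidate model fitted on the other folds; for
   training rows, from inner out-of-fold prediction (default 3–5 inner
   folds) within those folds. This stacked-generalization contract is the
   single most consequential choice the procedure leaves open: without it,
   the target model would see candidate predictions informed by a row's
   own measured concentration and the CV scores would be optimistic. A
   `naive` mode (in-sample candidate predictions) exists behind a flag for
   comparison. Candidate predictions are regenerated from the *current*
   feature set at every iteration; accepted columns are frozen as computed
   at acceptance.
2. **Evaluation.** The target model is refit on features ∪ {Ê_c} on the
   same outer folds and scored by mean CV R².
3. **Selection.** The best candidate (ties: lower mean RMSE, then element
   name order) is accepted iff it strictly improves the current best mean
   R² (tolerance 0 by default, configurable). The accepted-score
   trajectory is therefore strictly increasing by construction, and the
   final score never falls below the STR baseline.

Chained feature columns are passed on the **ppm scale**: every backend
scales or standardizes its inputs internally (glmnet, e1071 and PLS
explicitly; forests are scale-invariant), so the affine scale of one
appended column is immaterial, and keeping ppm avoids threading per-fold
target-scaler state through the feature path.

The **candidate pool** is restricted to elements whose STR accuracy
reaches a threshold (default mean CV R² ≥ 0.55; a score exactly at the
boundary is kept). All elements are still *predicted*; the filter governs
only what may be chained as an input. The aggregate used for the filter —
best learner per element (default) or the mean across learners — is
configurable, since either aggregation is defensible.

For held-out prediction, `fit_mtsc()` refits final models on the full
training split: chain features for the training rows come from inner
out-of-fold prediction, while the stored candidate models (fit on all
training rows) generate chain features for new spectra sequentially.

## Evaluation

R² and RMSE (√ of the mean squared error, in ppm) are computed per fold;
ΔR²% and ΔRMSE% = 100·(MTSC − STR)/STR are computed per fold and averaged,
and also from the fold means — both are reported, clearly labelled, since
they differ in general. STR and MTSC are compared per element by a paired
two-sided Wilcoxon signed-rank test on the k fold R² values: zeros are
dropped (classic Wilcoxon), the exact null distribution is used for
effective n ≤ 25 — computed by dynamic programming over doubled midranks,
so ties are handled exactly — and a tie- and continuity-corrected normal
approximation beyond. Labels are ns/*/** at p < 0.05 / 0.01 (a *** tier at
p < 0.001 is added for correlation matrices). Descriptive panels report
min/mean/max/SD and the integer CV% = round(100·SD/mean); spectral
similarity uses plain Euclidean distance with optional within-plant
summaries.

## The synthetic generator

`generate_dataset()` simulates what the algorithm needs and nothing more:
log-normal concentrations hitting a configured mean and CV (leaf ionome
panels are positive and right-skewed, with CVs of roughly 34–65% and
max/mean ratios near 3); Gaussian absorption signatures
g(λ) = a·exp(−(λ−c)²/2w²) subtracted from a flat 0.5 baseline in
proportion to the min–max-normalized concentration; additive Gaussian
noise; reflectance clipped to [0.01, 0.99] (the clipped fraction is
logged, and a warning fires if signatures are strong enough to clip more
than half the values). Dependent elements are links (linear or saturating
v/(1+v/v₀)) of their parents plus noise, clipped at zero, with **zero**
direct spectral loading — so any chaining gain is attributable to the
dependency structure, not to a hidden signature.

Two shipped scenarios:

* **G1** (`scenario_g1()`): 400 samples, 120 bands on 400–2,400 nm; A, B,
  C active with separated signatures (amplitude 0.18, width 90 nm — strong
  enough that a ridge model recovers each with CV R² well above 0.8);
  D = 0.9·A + noise (SD 10% of the signal SD), E a saturating function of
  B, F independent.
* **G0** (`scenario_g0()`): same panel, no signatures, no dependencies.

The validation studies in the test suite and the acceptance script run 20
replicate seeds of each scenario with 5 outer and 3 inner folds and
single-point "pre-tuned" grids (Ridge λ = 10⁻⁴ for candidate models; RF
with 300 trees, feature fraction 0.15, depth 8 for the target model) —
problem sizes chosen so a full replicate study completes in minutes on one
CPU; the package defaults remain k = 10 and 5 inner folds.

What G1 shows: a forest cannot extract D from ~119 derivative bands
directly, but the chained Ê_A feature lifts its CV R² substantially and
the true parent is selected first essentially always. What it does *not*
show: gains for linear target models. When the target model is Ridge, MTSC
accepts nothing on G1 — D = 0.9·A is itself a linear function of the
spectra, so a leakage-safe Ê_A column is redundant for a linear model.
This is a real property of honest chaining on linearly generated data, not
a defect: chaining pays off when the target model is nonlinear or the
feature space is too wide for it, which matches the observation that
bagged-tree learners benefit most from chained targets while ridge-type
learners benefit least.

## Known limitations

* **Selection bias under the null.** Forward selection re-uses the same
  CV folds for scoring and for the acceptance decision. With several
  near-null candidates, the maximum of their (noisy) scores exceeds the
  baseline roughly half the time, so with the candidate filter bypassed,
  G0 chains average well above zero length (~1.8 elements in the shipped
  null study) even though no candidate carries information. The 0.55 pool
  filter is what controls this in practice — under G0 the pool is empty
  and every chain is empty. Chain memberships should be read as greedy
  selections, not as significance statements; the Wilcoxon comparison of
  STR vs MTSC is the inferential summary.
* Gaussian-feature mixing is not radiative-transfer realism (no
  PROSPECT-style leaf optics); passing tests demonstrate algorithmic
  correctness, not field performance.
* The simulator's dependent elements have exactly zero spectral loading;
  real ionomes mix both pathways.
* Grubbs filtering assumes an approximately normal per-sample summary;
  heavy-tailed contamination of many samples at once violates the
  one-at-a-time outlier model.
* Min–max scaled test targets can fall outside [0, 1] by design; RMSE in
  ppm is unaffected, but users adding custom learners must not clip.

## Reproducibility

Every stochastic step (splits, folds, forests, simulators) is driven by an
explicit integer seed; repeated runs of `run_experiment()` with one
configuration produce byte-identical reports, which the test suite
asserts. `write_report()` emits the comparison table, the per-fold long
table and a JSON manifest (seeds, tuned configurations, pools, chains)
sufficient to replay a run exactly.
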