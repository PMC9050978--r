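---
title: "Quantifying lung-lesion heterogeneity on CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lung-lesion heterogeneity on CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctrad)
```

`ctrad` implements a complete 2-D CT radiomics analysis for lung lesions: a
compact panel of eight selected features plus diameter, a random-survival-
forest composite score, and the three validation axes that decide whether such
features deserve clinical attention — prognosis, association with semantic /
genetic / histopathological tumour profiles, and measurement reliability.
Because public lung-CT collections ship without the manually drawn ROIs such
analyses require, the package is built around a synthetic cohort generator
whose every clinical label traces back to image-generating parameters with
stated effect sizes, so each downstream claim is testable against a known
truth.

This vignette records the models, the tunable parameters, the numerical
choices, and the limits of what the synthetic evidence shows.

## The synthetic cohort generator

### Lesion phantoms

A phantom (`make_lesion_phantom()`) is a square frame (default 64 px at 1 mm
spacing) containing one lesion with the analytic boundary

$$ r(\theta) = R \,\bigl(1 + a \cos(f \theta)\bigr), $$

with radius $R$ in mm, spiculation amplitude $a \ge 0$ (dimensionless) and
$f$ lobes per revolution. The mask is the exact rasterisation of this curve,
so ground-truth shape quantities (circularity, diameter) are controllable.

The intensity field is built in four steps, all driven by one seeded
generator per call (no global RNG state leaks):

1. **Correlated texture.** White Gaussian noise smoothed with a Gaussian
   kernel of standard deviation `texture_corr_len` (px) and renormalised to
   `lesion_sd`. The correlation length is the single dial behind run-length
   texture (long runs of equal gray level come from smooth fields).
2. **Histogram shape.** The standardized field passes through the signed
   power transform $\mathrm{sign}(x)\,|x|^\gamma$ (`texture_gamma`, default
   1). Real lesions differ not only in texture scale but in the *shape* of
   their brightness distribution; without this axis, range-normalised
   histogram features are nearly constant across subjects and reliability
   analyses have no between-subject variance to measure.
3. **Internal structure.** A few small bright/dark inclusions
   (`n_inclusions`, default 3; amplitude `inclusion_amp`, default equal to
   the lesion contrast) are placed in the deep interior (kept at least 4 px
   from the boundary). They emulate vessels, calcifications, air bronchograms
   and necrotic foci, and they matter numerically: they anchor the minimum
   and maximum of the ROI intensity range from *inside* the lesion, so
   fixed-bin discretization does not hinge on which boundary pixels a
   segmentation happens to include.
4. **Point-spread function.** The composed image (background mean/sd plus
   lesion contrast `lesion_mean`) is blurred with a Gaussian PSF
   (`psf_sigma`, default 0.8 px) and rounded to integer intensities, giving
   the partial-volume edges of reconstructed CT rather than a step edge.

Repeat scans (`make_repeat_pair()`) translate image and mask by an integer
offset (patient repositioning) and add Gaussian acquisition noise that is
itself spatially correlated (`noise_corr_len`, default equal to the PSF):
noise in reconstructed CT passes through the same kernel as the signal and is
not white at pixel scale.

### Clinical linkage

Survival (`simulate_survival()`) follows an exponential proportional-hazards
model: with internally standardized features $z_f$ and configured log hazard
ratios $\beta_f$ per SD, subject $i$ has rate
$h_i = h_0 \exp(\sum_f \beta_f z_{if})$. Censoring is an independent
exponential whose rate solves $E[c/(c+h_i)] = q$ for the target censoring
fraction $q$ — the closed-form calibration is why the exponential (rather
than a Weibull) was chosen. Times are months, rounded to two decimals.

Profiles (`simulate_profiles()`):

* **Semantic flags** are deterministic thresholds on the generating
  parameters (default: spiculated ⇔ amplitude > 0.15, solid ⇔ contrast
  > 400, and stand-in links for lobular / juxtapleural / pleura-tag). They
  stand in for radiologist reads, which is exactly what they cannot
  emulate: observer variability.
* **Mutation labels** (EGFR/KRAS/ALK) come from a liability-threshold model.
  For prevalence $p$ and a target mutant-minus-wild mean shift $\delta$ (in
  normal-scores SD units of the named feature), the latent mixing weight has
  the closed form $r = \delta\,p(1-p)/\varphi(\Phi^{-1}(1-p))$, so the
  injected shift is exact, not tuned.
* **Grade** (ordinal 1–3) cuts a latent Gaussian $L = r z + \sqrt{1-r^2}\,
  \varepsilon$ at tertiles. The population Spearman correlation between the
  feature and the 3-level grade is available as a one-dimensional Gaussian
  integral, and `ctrad` inverts it numerically (`uniroot`) so the configured
  Spearman target (default 0.33) is the population value of the generated
  data. The attainable maximum for a tertile-coarsened grade is about 0.94.
* **Histology** is drawn independently from configured proportions; no
  feature link is injected by default.

Default cohort parameter ranges (radius 8–16 mm, spiculation 0–0.3,
correlation length 2–6 px, shape $\gamma$ 0.6–1.8, contrast 250–550, texture
sd 30–80, 1–5 inclusions) were chosen once as a plausible spread for lung
lesions at ~1 mm resolution; the correlation-length floor of 2 px reflects
that texture finer than the PSF cannot survive reconstruction. They are
study conditions, not fitting knobs.

### What the generator does not emulate

No anatomy (airways, vessels outside the lesion, chest wall), no 3-D
volumes, no scanner/kernel differences, no real observer reads of semantic
characteristics, and histogram/texture distributions far simpler than real
tumours. Passing tests therefore demonstrate that the *machinery* — features,
score, statistics — behaves correctly under known truth, with realistic edge
softness and internal structure; they do not certify performance on real CT.

## Segmentation

The workflow mirrors interactive practice but is fully deterministic:
`max_area_slice()` picks the largest-area slice (ties to the first);
`threshold_mask()` windows the intensity, keeps the largest 8-connected
component and fills holes; `refine_active_contour()` refines an
initialization with a morphological active contour:

* **Region method** (default): the binary level set of a two-phase
  piecewise-constant (Chan–Vese-type) energy. Boundary pixels flip toward
  the phase (inside mean $c_1$, outside mean $c_0$) they match better under
  weights $\lambda_1, \lambda_2$; one curvature-smoothing pass (alternating
  sup-inf/inf-sup operators over four line elements) per iteration.
* **Edge method**: morphological geodesic evolution under the stopping
  function $g = 1/(1 + (|\nabla G_\sigma * I|/s)^2)$ with $\sigma$ = 2 px. A
  shrinking balloon erodes the contour only where $g$ exceeds 0.5, with the
  sensitivity $s$ anchored at three times the median *background* gradient —
  so the balloon acts on background-flat pixels and stops at any real edge
  or interior texture; a gradient-attraction term pins the contour to edge
  ridges. No curvature smoothing by default (it erodes spiculations).

Both methods stop when the changed-pixel fraction falls below `tol`
(2e-4) or at `max_iter` (150), are post-processed to one filled component,
and signal `contour collapsed` if the foreground vanishes. Evolution is
confined to a morphological corridor of `band_px` (3) erosions/dilations of
the initialization: the operation refines a supplied contour rather than
re-detecting the lesion, and the corridor rules out leak-driven collapse
across locally weak boundary segments. All of these numbers are exposed in
`contour_params()`; none is stated by the analyses this package reproduces,
so they are documented package choices validated by the Dice properties in
the test suite (≥ 0.98 on clean phantoms, ≥ 0.9 across spiculation levels
and at noise half the lesion contrast).

## The radiomic panel

All texture features operate on `discretize()`d gray levels: fixed bin count
$G$ over the masked intensity range,
$\ell = \min(G, \lfloor G\,(x - \min)/(\max - \min)\rfloor + 1)$, constant
ROIs mapping to level 1. $G = 32$ by default; the analysis does not depend
on raw intensity units, and adding a constant to the image changes nothing
(verified as an invariant test).

* **First order** (`first_order()`): with $p(i)$ the level histogram,
  variance $\sum (i-\mu)^2 p(i)$; kurtosis $m_4/m_2^2$ in the Pearson
  convention (normal ⇒ 3), chosen because reported lesion values straddle 3;
  energy $\sum p(i)^2$ — histogram uniformity in $(0, 1]$. Variance is
  computed on discretized levels, not raw intensities: this is what makes it
  unit-free and comparable across scanners, and it is stated prominently
  because the same name often denotes the raw-intensity moment elsewhere.
* **Circularity** (`shape_circularity()`): $4\pi A / P^2$ with $A$ the pixel
  area and $P$ a weighted-step perimeter from Moore-neighbour boundary
  tracing with Vossepoel–Smeulders weights (0.980 axial, 1.406 diagonal,
  −0.091 per corner) plus a Steiner offset of $\pi \cdot$ spacing, because
  the traced polygon joins pixel centres half a pixel inside the true
  boundary. Naive pixel-edge counting biases disk circularity low by tens of
  percent; with these corrections a rasterised disk lands within 5% of 1 and
  a square within 0.05 of $\pi/4$.
* **Diameter** (`lesion_diameter()`): mean of the major and minor axes of
  the ellipse with the mask's normalized second central moments (pixels
  treated as unit squares, adding $\mathrm{spacing}^2/12$), rounded half away
  from zero to an integer in mm.
* **GLCM** (`glcm()`, `glcm_features()`): symmetric co-occurrence counts at
  distance 1 over the four principal directions, summed and normalised;
  maximum probability $\max p(i,j)$ and cluster shade
  $\sum (i + j - \mu_i - \mu_j)^3 p(i,j)$.
* **GLRLM** (`glrlm()`, `glrlm_features()`): maximal equal-level runs per
  direction, broken at the mask boundary; long-run emphasis
  $\sum R(i,j)\,j^2 / N_r$ and long-run high gray-level emphasis
  $\sum R(i,j)\,j^2 i^2 / N_r$, averaged over the four directions — the
  "mean" suffix is read as the directional average, standard 2-D practice.
* **Wavelet LRE** (`wavelet_approx_lre()`): one-level Haar transform of the
  ROI bounding box; the low-low subband is re-discretized (mask downsampled
  by requiring all four source pixels in-mask) and the directional-mean LRE
  computed there. Haar was chosen as the simplest orthogonal basis; the
  family is exposed in `feature_extraction_config()`.

Every GLCM/GLRLM value is checked against exhaustive pair/run enumeration
oracles to 1e-12 (relative, unit floor) on random ROIs, and the
direction-averaged features are exactly invariant to 90° rotation.

## The composite score

`fit_rsf()` grows `ntree` = 50 survival trees on bootstrap samples (with
replacement, same size as training; out-of-bag data unused). At each node,
`mtry` = ⌈√p⌉ randomly chosen features are screened over all midpoints of
sorted unique values — midpoints make tie-breaking deterministic — and the
split with the largest absolute standardized two-sample log-rank statistic
wins, subject to `nodesize` = 10 on both children and `nodedepth` = 4.
Terminal nodes store the Nelson–Aalen cumulative hazard of their in-bag
subjects on the grid of all training event times. The predicted risk
(`predict_mortality()`) is ensemble mortality: the tree-averaged leaf hazard
summed over that grid. `normalize_score()` rescales risks by the *training*
min/max to 0–100 and clips out-of-range test or external risks — clipping
rather than extrapolation keeps the printed score range meaningful, and
train-only normalization avoids leaking test information. Because splits
depend only on feature order, strictly monotone transforms leave the tree
structure invariant (tested). ntree/nodesize/nodedepth are taken as given;
the grid search that could produce them is out of scope.

## Prognosis evaluation

* `harrell_c()`: over pairs whose shorter observed time is an event,
  concordant when that subject has the higher score, 0.5 per score tie.
* `auc_t()`: cumulative/dynamic time-dependent AUC. Cases are events by
  horizon $t$, controls survive beyond $t$; both are weighted by inverse
  probability of censoring from the Kaplan–Meier censoring distribution
  (cases at $1/\hat G(T_i^-)$, controls at $1/\hat G(t)$). This estimator
  matches the "survival beyond $t$" phrasing of the question and reduces
  exactly to pair-counting ROC AUC when no one is censored (oracle-tested).
* `km_curve()` / `logrank_test()` wrap the survival package's product-limit
  estimator and two-sample log-rank test.
* `median_split()` labels scores ≤ median "low" — ties deterministically go
  low. `cox_hr_binary()` fits the one-covariate Cox partial likelihood with
  Breslow tie handling (adequate at the synthetic tie rates; simpler than
  Efron) and reports Wald 95% CIs on the log scale; monotone likelihoods
  (complete separation of event order) are refused with advice to use an
  exact method. `subgroup_hr()` recomputes nothing: the high/low split is
  fixed on the full cohort and refitted within subgroups, with per-row NA +
  reason when a subgroup cannot support the fit.

## Profile associations

`wilcoxon_de()` uses the exact two-sided rank-sum distribution when
min(n₁, n₂) ≤ 8 with no ties, otherwise the normal approximation with tie
and continuity corrections; the direction is the sign of the median
difference (present minus absent), "ns" when p ≥ α. `spearman_assoc()` uses
midranks and the t approximation. `association_table()` crosses every
feature with the five semantic flags, mutant-vs-wild per gene, pairwise
histology groups (a Kruskal–Wallis omnibus is reported alongside, since a
single three-group p-value needs an omnibus test), and Spearman for grade.
P-values are deliberately unadjusted — significance is reported per test at
two tiers (0.05, 0.01) — with optional Benjamini–Hochberg behind
`adjust = TRUE`. The effect size is the median difference, matching how such
results are printed, not a log-fold-change.

## Reliability

`icc()` is fixed to ICC(2,1) — two-way random effects, absolute agreement,
single measure — for all three comparisons; absolute agreement is the
conservative choice for method comparison, and the form is recorded in the
output. Negative estimates are reported as-is with a flag rather than
truncated. `bland_altman()` reports bias, SD of differences and
bias ± 1.96 SD limits. `reliability_study()` runs the full extraction on
both members of each pair for: repeat scans (correlated noise sd 5 — about
10% of typical lesion texture sd, a moderate same-session level — plus 2 px
repositioning), between-algorithm (region vs edge refinement of one
threshold initialization), and between-"operator" (refinement from dilated
vs eroded initializations standing in for two readers). Features with
ICC ≥ 0.8 are flagged robust.

## Problem sizes and determinism

The bundled drivers and the acceptance script use a demonstration study of
90 development + 40 external + 20 test-retest subjects at 64 px frames —
sizes chosen so a complete run takes about a minute while every stage has
enough events and pairs to estimate its quantities. Recovery properties
(injected log-HR, mutation shift power, grade correlation, calibration) are
tested at n = 500–1000. Every stage takes an explicit seed; identical
configurations reproduce every artifact byte-for-byte, which the test suite
asserts on the full pipeline.

## Known limitations

Single 2-D slice per lesion; binary lesion support with additive texture
rather than infiltrative margins; semantic labels are parameter thresholds,
not reads; histology carries no injected image signal; the grade target
cannot exceed ~0.94 by construction; Breslow ties only; no ICC confidence
intervals (point estimates only); feature magnitudes depend on the
discretization (G = 32 default) and are not comparable to values computed
under other binning conventions.
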