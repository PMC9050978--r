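# ctrad — CT radiomic heterogeneity analysis for lung lesions

Lung cancers that look alike under a microscope can behave very differently,
and routine CT reads reduce all that morphology to a diameter and a handful of
semantic adjectives. Radiomics promises more — quantitative shape, histogram
and texture descriptors — but features only earn clinical attention if they
(1) predict outcomes, (2) track biological tumour profiles, and (3) survive
remeasurement. `ctrad` is an R implementation of that whole argument as one
tested analysis pipeline, aimed at methodologists who want every step of such
a study exercisable on synthetic data with known ground truth.

The pipeline:

* **Synthetic cohorts** — lesion phantoms with an analytic boundary
  *r(θ) = R(1 + a·cos(fθ))*, correlated Gaussian texture with a tunable
  correlation length and histogram shape, interior vessel/calcification-like
  inclusions, a scanner point-spread function, repeat scans with correlated
  acquisition noise, and clinical tables whose survival (exponential
  proportional hazards, log-HR per SD of named features), mutation labels
  (liability-threshold mean shifts) and ordinal grade (latent-Gaussian
  Spearman target) are all linked to the image-generating parameters.
* **Segmentation** — maximum-area slice selection, intensity-window
  initialization, and deterministic region-based (Chan–Vese-type) or
  edge-based (geodesic, gradient-stopped) morphological active contours.
* **Features** — the eight selected descriptors: circularity (4πA/P² with a
  corner-corrected traced perimeter); variance, Pearson kurtosis and energy
  (Σp²) of the 32-level histogram; GLCM cluster shade and maximum
  probability; GLRLM long-run high gray-level emphasis mean (LongHEM); a
  one-level Haar approximation-subband long-run emphasis; plus the integer
  mm diameter from the moment ellipse.
* **Composite score** — a from-scratch random survival forest (ntree 50,
  nodesize 10, nodedepth 4, log-rank splitting over midpoint thresholds,
  Nelson–Aalen leaf hazards); ensemble mortality rescaled to 0–100 on the
  training range.
* **Evaluation** — Harrell's C, IPCW time-dependent AUC (cumulative/dynamic),
  Kaplan–Meier median-split stratification with log-rank tests, binary Cox
  hazard ratios with subgroup tables; Wilcoxon/Spearman differential
  expression of features against semantic flags, EGFR/KRAS/ALK status,
  histology and grade; ICC(2,1) + Bland–Altman reliability across repeat
  scans, segmentation algorithms and operators.

## A worked example

```r
library(ctrad)

# one lesion: moderately spiculated, textured phantom
ph <- make_lesion_phantom(phantom_config(spiculation_amp = 0.2,
                                         spiculation_freq = 6, seed = 42))

# segment it from a threshold initialization and check against ground truth
init <- threshold_mask(ph$image, low = 300)
seg  <- refine_active_contour(ph$image, init, contour_params("region"))
dice(seg, ph$mask)
#> [1] 0.9738562

# extract the radiomic panel
extract_all(ph$image, ph$mask)
#> <feature_vector>
#>   circularity          0.613835
#>   variance             21.3577
#>   kurtosis             4.45232
#>   energy               0.0719376
#>   cluster_shade        207.743
#>   maximum_probability  0.0497041
#>   longhem              451.874
#>   a_lre                1.34154
#>   diameter_mm          25
```

Circularity 0.61 reflects the injected spiculation (a clean disk phantom
scores ≥ 0.95); the 25 mm diameter matches the 12 mm generating radius; the
texture values are on the 32-level discretized scale.

The full study lives in the numbered drivers under `analysis/` (simulate →
segment/extract → score → prognosis → associations → reproducibility), each a
thin script over package functions that prints what it found and writes
tables under `results/`. On the default seeds the demonstration study (90
development, 40 external, 20 test-retest subjects) gives a training C of
0.79, held-out C of 0.58 (n = 30) and external C of 0.60, a development
high-vs-low hazard ratio of 3.3 (log-rank p ≈ 2e-5), recovery of the injected
EGFR–kurtosis shift (p ≈ 3e-6), and 8/8 features with ICC ≥ 0.8 for both
repeat scans and between-algorithm segmentation (repeat ICC range
0.82–1.00). `run_full_pipeline()` performs the same sequence as one call and
writes a manifest; identical configurations reproduce every artifact
byte-for-byte.

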