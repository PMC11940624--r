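---
title: "Ultrasound radiomics for P/LP variant prediction: models, conventions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ultrasound radiomics for P/LP variant prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the models
and statistical procedures it implements, the conventions chosen where
several are defensible, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the known
limitations. Nothing stated here as an empirical result goes beyond
what the test suite and the acceptance script themselves compute.

## 1. The problem and the pipeline

Germline pathogenic/likely-pathogenic (P/LP) variants in the major
breast-cancer predisposition genes change surgical decision-making, but
genetic testing is slow and unevenly available. The working hypothesis
of ultrasound radiomics is that P/LP-associated biology leaves a
quantitative trace in B-mode texture of the tumor and its
microenvironment. The pipeline is:

1. **ROIs** — the segmented tumor core, and the tumor plus a
   peritumoral ring of 0.5–1 cm, built by morphological dilation and
   trimmed by an exclusion mask (skin, pectoral muscle).
2. **Texture features** — 278 Mazda-convention descriptors per ROI
   (histogram, GLCM, GLRLM, causal autoregression, Haar wavelet
   energies).
3. **Selection cascade** — Mann–Whitney + Benjamini–Hochberg,
   Spearman redundancy pruning, LASSO logistic regression with
   10-fold cross-validation.
4. **Rad-Score** — the linear combination of the LASSO survivors
   weighted by their coefficients; `radscore1` for tumor-only,
   `radscore2` for tumor+peritumoral features.
5. **Evaluation** — four classifiers on {Rad-Score, Ki67 ≥ 20%} with a
   stratified 75/25 split and a full diagnostic metric panel.

## 2. The synthetic image model

Real patient images cannot be redistributed, so every stage is
validated on a generator (`lesion_params()`, `simulate_lesion_image()`,
`simulate_cohort()`) with this model:

* a piecewise-constant **echogenicity map**: background mean 1, an
  elliptical lesion at `echogenicity_contrast` (< 1: hypoechoic, the
  typical malignant appearance), optionally a darkened posterior
  shadow band;
* lesion margins perturbed by a low-order random Fourier series in
  polar angle (`margin_irregularity`, fraction of the radius), giving
  microlobulated, irregular outlines;
* multiplicative **Rayleigh speckle** with unit mean
  (`speckle_scale`), then Gaussian smoothing with
  `texture_correlation_length_px` — the single class-dependent texture
  knob.

This is the simplest model that reproduces ultrasound-like granularity
with one interpretable texture parameter. It deliberately omits
point-spread-function physics, depth-dependent attenuation and gain,
probe-geometry effects, and real anatomical clutter. The class effect
enters **only** through texture parameters (and optionally contrast),
never through mask geometry, so feature-recovery tests are
unambiguous: a pipeline that separates the classes can only have done
so through texture.

**Cohort defaults** mirror the structure of the study cohort this
workflow was designed around: 50 positive / 38 negative lesions;
Ki67-high rates 46/50 and 26/38 drawn as Binomial; machine A/B
assigned with probability 0.5 independently of class (so batch-effect
checks have a true null). No quantitative description of between-class
texture differences exists for real data, so the planted effect sizes
are free parameters chosen once: per-lesion correlation length drawn
from N(2.4, 0.3²) px for carriers vs N(1.2, 0.3²) px for
non-carriers (a deliberately *strong*, cleanly recoverable effect),
contrast N(0.45, 0.05²) in both classes, speckle scale 0.35, 128×128
images at 0.35 mm/px with semi-axes ≈ (17, 14) px jittered ±15%.

**What a green end-to-end test establishes:** that the implementation
recovers a strong planted texture difference through the entire chain
(extraction → selection → Rad-Score → classification) and stays
calibrated (AUC ≈ 0.5) when no effect is planted. It establishes
nothing about predictive performance on real patients; the published
cohort-level AUCs are not reproducible without the images and are not
targets of this package.

## 3. Imaging conventions

* **Coordinates** — row-major, pixel-aligned masks, no sub-pixel
  contours. Isotropic spacing is required; anisotropic inputs are
  rejected rather than silently resampled.
* **I/O** — PNG only (8/16-bit grayscale); the environment provides no
  TIFF codec. 16-bit output uses a minimal in-package PNG encoder
  because the available writer stores 8-bit only; round-trips are
  exact and tested. Color images are rejected.
* **Peritumoral ring** — dilation by a Euclidean disk of radius
  `round(margin_mm / spacing_mm)` px; exact by nearest-boundary
  distance, verified against brute-force disk rasterization. The
  margin must lie in [5, 10] mm; the default 7.5 mm is the midpoint of
  the protocol's 0.5–1 cm band. A radius rounding below 1 px is an
  error (spacing too coarse), not a silent no-op.
* **Denoising stand-in** — the original workflow used an unversioned
  commercial denoiser; reproducibility is preferred over fidelity, so
  the package substitutes a median filter (radius 1 by default) that
  is **off** unless requested.
* **Normalization/quantization** — per-ROI `mu3sigma`: clamp in-mask
  intensities to μ±3σ, bin linearly into Ng = 64 levels (the classical
  co-occurrence convention; Ng configurable as a power of two ≥ 4).
  This makes all downstream features exactly invariant under positive
  affine intensity transforms, which the suite asserts end-to-end.
  Whether the original normalization was global or per-ROI is
  unknowable from the outside; per-ROI is implemented and flagged
  here. σ = 0 (constant ROI) maps everything to level 0 with an
  explicit warning flag.

## 4. Feature conventions

The registry (`feature_registry()`) is fixed and deterministic:
9 histogram + 220 GLCM (11 Haralick statistics × offsets
(0,d),(d,0),(d,d),(d,−d) for d = 1..5) + 20 GLRLM (5 × 4 directions) +
5 AR + 24 wavelet (4 bands × 6 scales) = **278 features**. Printed
sources for this kind of workflow quote both "306" and "310"
variables; the two numbers are mutually inconsistent and neither
pins down a feature list, so the registry implements the classical
set and records its own count in the manifest instead of forcing
either figure.

* **Histogram** — population moments (kurtosis is excess) and
  nearest-rank percentiles (`ceiling(p·n)`-th order statistic) of the
  *normalized* in-ROI intensities; under `mode = "none"` these are raw
  intensities. Constant ROIs have undefined skewness/kurtosis (NA,
  never a silent 0).
* **GLCM** — pairs accumulated symmetrically, normalized to sum 1;
  gray levels indexed 1..Ng for the moment-type statistics; natural
  logarithms; 0·log 0 := 0. Correlation is set to 0 when a marginal
  SD vanishes (a degenerate single-entry matrix yields AngScMom 1,
  Contrast 0, entropies 0).
* **GLRLM** — runs are maximal constant-level segments along scanlines
  in the four principal directions, broken at mask boundaries;
  `Fraction` is runs per traversed in-mask pixel. The conservation law
  Σ l·R(g,l) = in-mask pixels holds by construction and is asserted.
* **AR model** — causal four-neighbor least squares (W, NW, N, NE) on
  mean-centered levels; requires ≥ 32 usable pixels, else an
  undefined marker; rank-deficient designs yield θ = 0, Sigma = 0
  with a flag.
* **Wavelets** — orthonormal 2×2 Haar blocks on the bounding-box
  patch, out-of-mask pixels filled with the in-mask mean; valid
  positions only (a trailing odd row/column is dropped, no
  periodization); band labels give horizontal-then-vertical frequency
  content (HL responds to vertical edges). Energies are mean squared
  coefficients over positions whose support touches the mask; scales
  deeper than the bounding box yield NA markers. Parseval holds
  exactly at scale 1 on even full-mask patches and is asserted.

Printed coefficient tables mangle names (`X.S.0.1.Contrast`,
`X135dr_GLevNonU`, `ZWavEnLL_s6`, `_s.3`); `canonical_feature_name()`
maps both forms to the registry spelling, so published Rad-Score
coefficients can be used directly.

## 5. Selection cascade

* **Mann–Whitney** — U = R_a − n_a(n_a+1)/2 on pooled mid-ranks.
  Exact enumeration of assignments when min(n, m) ≤ 8 *and* the
  assignment count is ≤ 1e5 (enumeration is infeasible for extremely
  unbalanced designs, where the approximation is excellent anyway);
  otherwise the normal approximation with tie correction and
  continuity correction. Two-sided p is the doubled smaller tail,
  capped at 1.
* **Benjamini–Hochberg** — the standard step-up adjustment
  (`stats::p.adjust`); survivors have adjusted p strictly below
  0.050. Note the adjustment is *not* idempotent as a map on p-values
  (re-adjusting inflates further); the suite asserts the properties
  that do hold: elementwise inflation, bound at 1, order
  preservation.
* **Spearman pruning** — a greedy rule made fully deterministic:
  repeatedly locate the pair with the largest |ρ| (ties broken by
  registry order) and drop its member with the larger mean absolute
  correlation against all currently retained features (ties drop the
  later feature). Constant features are dropped first, with a reason.
  The postcondition (all pairwise |ρ| ≤ 0.9) is auditable and
  asserted on every run.
* **LASSO** — glmnet's binomial path from the data-derived λ_max
  downward; mean binomial deviance over 10 stratified, seeded folds;
  λ at minimal mean deviance by default (the 1-SE rule is available
  by `rule = "1se"` — the minimal-deviance reading is the default
  because the tuning-curve presentation this workflow follows does
  not name a rule). Standardization statistics are computed globally
  before CV (flagged: per-fold standardization is the leakage-free
  alternative); coefficients are reported on the standardized scale.
  A single surviving feature falls back to an unpenalized logistic
  fit, since a one-column design poses no selection problem.
* **Scope** — the cascade runs on the *full cohort* by default, which
  is what the protocol it reproduces states; this leaks label
  information into feature selection and will optimistically bias
  held-out metrics. `scope = "train_only"` with a train index gives
  the leakage-free variant; the default is fidelity, the switch is
  the caveat made executable.

## 6. Rad-Score and evaluation

The Rad-Score is Σ β_i x̃_i with **no intercept** — it is a relative
risk score, and any offset is absorbed by the downstream classifiers;
adding one would only shift every lesion equally.

Ki67 enters as the binary ≥ 20% category, matching how proliferation
is dichotomized in the cohort table this workflow mirrors.

Classifier hyperparameters are unstated upstream; the defaults are
field-standard and overridable: 500 bagged Gini trees with
mtry = ⌊√p⌋; 100 rounds of gradient boosting on depth-1 stumps with
shrinkage 0.1 and Newton leaf updates; KNN with k = 5 on standardized
predictors; soft-margin RBF-SVM with C = 1, γ = 1/p, solved exactly
via its quadratic-programming dual (a 1e-8 ridge keeps the kernel
matrix positive definite). Every stochastic fit is seeded. No
forest/boosting/SVM package is available in this environment, so
those learners are implemented in-package; with two predictors the
compact implementations are exact enough to be validated by the
perfect-separation, null-calibration and importance tests.

Decision thresholds: 0.5 posterior for probability-type scores, 0 for
the SVM decision value. The accuracy CI is the exact (Clopper–Pearson)
binomial interval. "Feature importance (1-AUC)" has no published
definition; it is implemented as **permutation importance on the
1−AUC scale**: importance_j = 1 − mean AUC over R seeded permutations
of predictor j in the test partition. This has the two properties the
label suggests: a non-influential predictor scores exactly
1 − AUC_full, and permuting a sole perfect predictor drives the term
toward 0.5. A single-class test partition yields an NA AUC with the
confusion-based metrics still reported.

Reported metrics come from a **single** stratified 75/25 split per
seed (75% = `round(n_class · 0.75)` per class). Whether upstream
numbers were averaged over repeated splits is ambiguous; one split per
seed is implemented, and averaging over seeds is trivial for the
caller.

## 7. Cohort statistics

The group-comparison table uses Pearson's χ² **without continuity
correction** for categorical variables — the uncorrected form
reproduces every published categorical p-value from the printed group
counts exactly to 3 decimals, while the Yates-corrected form does not
(e.g. it would give ≈ 0.010 instead of 0.005 for the Ki67 2×2 table),
which settles the otherwise-unnamed test choice. Ages are compared by
medians plus the Mann–Whitney p (consistent with the nonparametric
choice made for features; a t-test cannot be excluded but cannot be
verified without raw ages). The machine batch-effect screen is a
per-feature Welch t-test with the summary criterion "no batch effect
iff min p > 0.050" — faithful to the protocol it mirrors, but note
that with hundreds of features the minimum of null p-values is
routinely below 0.05, so the flag is conservative by construction.

## 8. Numerical choices and degenerate inputs

* Quantization maps the clamp boundaries to levels 0 and Ng−1;
  `floor` binning with the top edge clamped.
* 0·log 0 := 0 throughout; entropies in nats.
* Undefined features (too-small ROI for a wavelet scale or the AR
  design, constant-ROI moments, empty GLCM offsets) propagate NA
  markers; selection drops them with an audit reason; nothing is
  silently zeroed.
* Empty survivor sets are valid results at every cascade stage; a
  halted cascade yields the empty linear combination (Rad-Score 0 for
  every lesion), which downstream evaluation handles and which is what
  the null-calibration test exercises.
* Exact enumeration limits, fold assignment, bootstrap draws and
  permutations all derive from explicit seeds; every generator
  restores the caller's RNG state.

## 9. Limitations

* The image model is a texture phantom, not a physical B-mode
  simulator; transfer of any quantitative result to clinical images is
  out of scope.
* The full-cohort selection scope reproduces a known leakage caveat by
  design (see §5).
* The GLCM/GLRLM/AR/wavelet conventions follow the classical Mazda
  definitions as documented here; other radiomics toolkits differ in
  binning, aggregation and naming, and numerical agreement across
  toolkits is not expected.
* The 278-feature registry is a documented reconstruction; the exact
  upstream feature list is not recoverable (its printed counts
  conflict), so published per-feature coefficients can be *applied*
  (via name canonicalization) but not re-derived.
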