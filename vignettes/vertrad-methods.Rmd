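---
title: "Methods: radiomics and segmentation evaluation for fractured vertebral bodies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomics and segmentation evaluation for fractured vertebral bodies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and design

`vertrad` implements the quantitative machinery used to study vertebral
compression fractures on CT: segmentation training losses and agreement
metrics, a 280-feature IBSI-style radiomics extractor, a
segmentation-robust feature-selection cascade ending in a cross-validated
logistic LASSO, and the published 12-feature malignancy signature with its
diagnostic statistics. Deep-network training and inference (the detector
and segmenter that would produce automatic masks in a clinical pipeline)
are deliberately out of scope: the package computes the inputs and targets
such networks consume (MIPs, crops, cutouts, propagation labels) and
accepts externally supplied masks for evaluation.

The package is written in base-R/S3 style. The model-construction side
follows the classic R modelling idiom — `fracture_signature()` is a single
fitting function returning a classed object with `print`, `summary`,
`coef` and `predict` methods, and `model_spec` objects are directly
predictable — while the image-processing side (phantoms, volumes, MIPs,
losses, metrics, features) is a toolkit of plain functions, which is the
natural shape for pipeline stages that do not estimate anything.

# The synthetic phantom cohort

No patient data ship with the package; every downstream stage is exercised
on synthetic vertebra phantoms.

A phantom is an elliptic-cylinder vertebral body (posterior elements are
omitted, because reference segmentations of fractured vertebrae are drawn
around the vertebral body only) with:

* a cortical shell (default 1.5 mm, 800 HU),
* a trabecular interior (default 150 HU) carrying a correlated Gaussian
  texture (smoothed white noise, ~1 mm correlation length, SD 20 HU),
* global additive white noise (SD 20 HU),
* fracture-type appearance: every fracture compresses the body height by
  `fracture_compression_frac` (default 20 %); *acute benign* adds a
  sclerotic band (+250 HU over the central 30 % of the height);
  *malignant* inserts a lytic sphere (default radius 6 mm, −20 HU) centred
  on the lateral cortex so that it breaches the shell; *chronic benign*
  adds nothing further.

The default HU constants were chosen so attenuation-based features separate
the classes clearly; they are configurable per `phantom_params()`. The
default grid is 96×96×64 voxels at 0.5×0.5×1 mm so whole suites run in
minutes. All generators are pure functions of `(params, seed, label)`.

What the phantom does **not** emulate: CT physics (beam hardening,
reconstruction kernels, partial-volume blur at the cortex), anatomical
shape variation beyond affine jitter, multi-vertebra scenes with touching
bodies, and the morphological heterogeneity of real fractures. Passing
tests on phantoms therefore demonstrates the correctness of the
*computations*, not clinical performance.

## Observer re-segmentations

Repeat segmentations by different readers are emulated by perturbing the
truth mask's boundary: the voxel-centre signed-distance function of the
mask (computed by an exact Euclidean distance transform, shifted half a
voxel so the continuum boundary lies between voxel centres) is compared
against a smooth Gaussian random field (white noise smoothed at 4 mm,
scaled to SD `displacement_mm / 2` and hard-clamped at
`displacement_mm`). The boundary therefore never moves farther than the
requested displacement along its normal, the perturbation is spatially
smooth like human contouring variation, and the largest connected
component is kept so topology is preserved. A consequence of voxelisation:
displacements below half a voxel cannot flip any voxel, so sub-voxel
perturbations on coarse grids may return the input mask unchanged.

# Standardisation: resampling and discretisation

Features are computed at a common voxel spacing, default 0.29×0.29×0.70
mm. Intensities are interpolated trilinearly and masks by nearest
neighbour (`floor(x + 0.5)` rather than `round()`, because half-to-even
rounding duplicates some source voxels and skips others); the output grid
has `round(n * spacing / target)` voxels per axis, preserving the physical
extent to within one voxel per axis. The interpolator is a convention
choice: the published protocol does not state one.

Grey levels are discretised to 64 bins over the masked mean ± 3 SD (mean
and SD over the mask only, a radiomics convention; the sample SD is used).
Bins are half-open with the final bin right-closed; out-of-range values
clip to the first/last bin; a constant region (SD = 0) maps everything to
the middle bin, a documented degenerate rule.

# The 280-feature catalogue

The extractor computes, on the original image: morphology (15), local
intensity (2), intensity statistics (22), intensity histogram (23), GLCM
(25), GLRLM (16), GLSZM (16) and NGLDM (17); and on each of two
Laplacian-of-Gaussian filtered images (σ = 1 mm and 2 mm): local
intensity, statistics, histogram and GLCM (72 each). The total is
136 + 2×72 = 280. Feature definitions follow IBSI; the catalogue is a
package constant (`feature_catalog()`) and includes every feature of the
published signature. The exact family-wise composition of the original
280-feature list was never published (only the total and the ten families
appearing in the signature are known), so this catalogue is the package's
own reconstruction under those constraints; with standard IBSI family
sizes the published families alone cannot reach 280, hence the GLCM family
is also computed on the LoG images.

Numerical choices worth knowing:

* **Morphology** is voxel-based: volume = voxel count × voxel volume;
  surface area counts exposed voxel faces, which overestimates smooth
  surfaces by a staircase factor (a sphere's sphericity evaluates to ~0.66
  rather than 1) — consistent across cases, so relative comparisons stand.
  Axis lengths are `4 * sqrt(lambda)` from the population covariance of
  voxel centres. The maximum 3-D diameter scans surface voxels extremal
  along the 13 grid directions (exact for convex axis-aligned bodies,
  a slight underestimate otherwise).
* **Local intensity peaks** are spherical means over a 1 cm³ sphere,
  computed by FFT convolution; voxels outside the image are excluded from
  the mean.
* **LoG filtering** is separable Gaussian smoothing (σ in mm, spacing
  aware) followed by second central differences per axis (1/mm²), scaled
  by σ² so the response to a blob is extremal when the filter scale
  matches the blob scale. Constant volumes map to exactly zero.
* **GLCM**: 13 unique directions at distance 1, symmetrised, matrices
  averaged (directions with no valid pair are skipped); correlation is
  defined as 1 for a constant region.
* **GLRLM** merges run counts over the 13 directions; run percentage
  divides by `n_voxels * 13`.
* **GLSZM** zones are 26-connected components of equal level; **NGLDM**
  uses the 26-neighbourhood with coarseness α = 0 and column index
  `k + 1`.
* Degenerate denominators (zero variance, zero mean, empty robust range)
  return 0, so every phantom yields 280 finite values.

# The selection cascade and the signature

`fracture_signature()` applies, in order:

1. **Zero-variance filter** — exact, after rounding to 12 significant
   digits.
2. **Standardisation** — zero mean, unit sample SD, learned on training
   data and reused unchanged on any table scored later (the fitted model
   carries its standardizer).
3. **Stability filter** (when repeat tables from observer masks are
   supplied) — a feature is kept iff its Lin concordance correlation
   with *every* repeat exceeds 0.90. The aggregation across repeats was
   left open in the published protocol; the minimum is the conservative
   choice. CCC uses population (1/n) moments, Lin's original estimator;
   degenerate cases: two constants with equal means give 1, any other
   constant input gives 0. Because CCC is invariant under a common affine
   transform, filtering before or after standardisation is equivalent.
4. **Correlation pruning** — pairs with |Pearson r| > 0.90, visited in
   descending |r|; the member with the larger univariable p-value is
   dropped. The univariable test is a two-sided Mann–Whitney rank-sum test
   against the label (rank-based and scale-free; the published protocol
   does not name its test — a logistic-Wald p would order pairs almost identically).
5. **Logistic LASSO** — 100 log-spaced λ values from just above λ_max down
   four decades; stratified, seeded 5-fold CV on binomial deviance.
   Because CV deviance is a noisy estimate, deviances within one CV
   standard error of the minimum are treated as tied and ties resolve
   toward the larger λ (the sparser model) — the familiar one-standard-
   error rule. Selecting strictly at the minimum systematically keeps
   noise features in sparse-recovery experiments. The model refits on all
   data at λ*, and the decision cutoff is set by the Youden index on the
   training scores.

The published 12-feature signature ships as a JSON data file
(`published_model()`): intercept −0.176, cutoff 0.328, coefficients as
released. Its training-cohort standardisation parameters were never
published, so the spec carries no standardizer and scoring expects
pre-standardized inputs — applying the published coefficients to new raw
data is explicitly not reproducible.

# Diagnostic statistics

AUC is the Mann–Whitney concordance probability with half credit for ties
(equal to the trapezoidal area under the empirical ROC); its CI and the
paired comparison use DeLong structural components. The Youden cutoff
scans midpoints between adjacent distinct scores with `score >= cutoff`
positive, ties toward the lowest cutoff; `classify()` calls the tie at the
cutoff malignant (the published description does not state the tie rule, and the linear
score — not a logistic transform of it — is thresholded, consistent with
the signature being described as a weighted linear combination).
Proportions get Wilson 95 % intervals; the exact McNemar p is the capped
two-sided binomial tail `min(1, 2 P(X <= min(b, c)))`.

# The parity experiment

The package's end-to-end check mirrors the automated-vs-expert comparison:
train one signature on features from truth masks, then score a held-out
half under truth masks and under observer-perturbed masks, comparing AUCs
with the DeLong test. Study conditions, chosen once: 60 cases (30 acute
benign, 30 malignant), 48×48×28 voxels at 0.7×0.7×1.25 mm, extraction at
native spacing, and *moderated* lesion/sclerosis contrast (lytic lesion 70
HU against trabecular 150 HU; sclerotic band +50 HU). At the generator's
full-contrast defaults both truth-mask and 3-mm-perturbed scoring are
perfect (AUC = 1.0) and the comparison is uninformative; moderating the
contrast puts the task off that ceiling so boundary corruption has a
measurable effect, while sub-voxel (0.5 mm) perturbations still leave
parity intact (DeLong p ≫ 0.05). Magnitudes remain seed-dependent — the
direction of the effect, not its size, is the reproducible claim.

Problem sizes throughout the test-suite (40×40×26 to 48×48×28 grids,
native-spacing extraction) are the package's chosen defaults for
exercising every code path at desk scale; the full-resolution pipeline
(default grid, resampling to 0.29×0.29×0.70 mm) runs unchanged, only
slower (~2.5 M voxels per case).

# Known limitations

* Voxel-face surface area (and the shape ratios built on it) carries a
  systematic staircase bias relative to mesh-based IBSI morphology.
* The maximum 3-D diameter is a deterministic approximation (extremes
  along 13 directions).
* The per-case CSA is the total cross-sectional area over axial slices
  (equivalently volume / slice thickness), matching one-number-per-case
  reporting; a per-slice variant is available
  (`csa_error(per_slice = TRUE)`). The printed ASD summation formula carries a
  typographical index mismatch; the package implements the verbal
  definition, one-sided A→B by default with a symmetric
  option.
* The propagation-label rule (union of neighbours within the window,
  eroded once per slice of distance beyond the first) is one concrete
  instantiation of a mechanism described only qualitatively in the published protocol;
  it is isolated behind `make_propagation_label()` so alternatives can be
  swapped.
* Histogram equalisation in the MIP preprocessing is global, and region
  growing keeps supra-threshold components of at least 27 voxels; both are
  convention choices where only the operation itself is named in the published protocol.
* Phantoms are not CT physics; see above.
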