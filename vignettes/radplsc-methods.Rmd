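---
title: "Methods: paired-modality radiomics, PLSC inference and lesion mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-modality radiomics, PLSC inference and lesion mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the generative
model behind the synthetic cohorts, the exact conventions used by the
168-feature radiomics extractor, the PLSC latent-variable inference, the
perceptron classifier and its validation, and the lesion-mapping and
robustness procedures — together with the numerical choices and the
limitations a user should know about.

## The problem

A dominant intra-prostatic lesion (DIL) appears hypo-intense and
texturally distinct from normal glandular tissue (NT) on both T2-weighted
images and ADC maps. Given co-registered volumes of both modalities and a
DIL contour with a mirrored contralateral NT contour, the analysis asks:
which texture information is shared between the modalities, does it
discriminate DIL from NT, and can a compact classifier trained on that
information localise the lesion in new images?

## Synthetic cohorts

No patient data are packaged; every stage is exercised on simulated
subjects built by `generate_cohort()`.

* **Texture model.** Each modality volume is a Gaussian random field:
  white noise smoothed in-plane with a Gaussian kernel whose standard
  deviation sets the correlation length, restandardised to unit marginal
  SD, then scaled and shifted to the tissue's SD and mean. A shared latent
  noise field, mixed in with weight `cross_modality_coupling` (default
  0.6), makes the two modalities correlated — the structure PLSC is
  designed to find.
* **Lesion.** An ellipsoid (in-plane radius 7 voxels, z semi-axis 2 by
  default) implanted left of the midline. Inside it, the mean drops by
  `effect_size` NT-SDs (hypo-intensity) and the correlation length grows
  by 50% per unit effect (coarser texture). The NT mask is the DIL mask
  mirrored across the x midline, so both regions have identical size and
  shape. With `effect_size = 0` the lesion branch is skipped entirely:
  DIL and NT are then draws from one process, which the test suite uses as
  the exchangeability null.
* **Defaults as study conditions.** 117 subjects, 64 x 64 x 12 voxel
  volumes, T2W NT mean 100 / SD 15 (arbitrary units), ADC NT mean
  1.8e-3 / SD 2.5e-4 mm²/s (typical peripheral-zone values; at the default
  `effect_size = 2` the lesion ADC mean of ~1.3e-3 mm²/s is in the range
  reported for clinically significant cancer), correlation length 1.5
  voxels, b-values {50, 400, 800} s/mm². The literature gives no
  quantitative DIL/NT texture statistics to copy, so the effect size is an
  explicit knob chosen once; 2 NT-SDs is a visibly conspicuous lesion, the
  regime in which the reference analysis operates.
* **DWI.** Diffusion series follow `S(b) = S0 exp(-b * ADC)` exactly
  (optional Gaussian noise, off by default). The extraction stage re-fits
  ADC from these series by per-voxel ordinary least squares of `log S` on
  `b`, so the log-linear fitting path is exercised end to end; voxels with
  non-positive signal get ADC 0 and a QC flag rather than a log of a
  non-positive number.
* **What the generator does not emulate.** Anatomy (no gland, zones or
  organs), MR physics (no bias field, coil profile or Rician floor),
  inter-subject heterogeneity (every subject shares the lesion geometry
  and contrast), and registration error (modalities are generated
  co-registered, which replaces the affine co-registration a real pipeline
  would need). Passing tests therefore demonstrate correctness of the
  computations and calibration of the inference under a controlled model —
  not clinical performance.

## Harmonization

Scanner gain affects weighted images arbitrarily, so each volume is
divided by the mean intensity over the subject's NT mask (`harmonize()`),
making the NT mean exactly 1 and cancelling any global gain; the test
suite asserts feature-level invariance to such gains. By default the ADC
map is harmonized too (normalisation also suppresses residual
acquisition effects on ADC); `harmonize_adc = FALSE` keeps ADC in
physical units. The same choice must be used at training and mapping
time, and the mapping functions take it as an argument for that reason.

## The 168-feature descriptor

Features are computed per ROI per modality in a fixed order (see
`feature_names()`): IBHF 9, GLRL 7, LAWS 18, DOST 18, LBP 6, 2DWT 48,
2DGF 40, GLCM 22. Conventions shared by all families:

* **2D per slice, averaged over slices.** All transform and matrix
  families operate on each axial slice's bounding box and average the
  resulting features across slices holding at least 16 in-mask pixels;
  the intensity histogram family pools the full 3D in-mask voxel set.
* **Mask handling.** Texture is computed on the in-plane bounding box of
  the mask with out-of-mask pixels replaced by the slice's in-mask mean
  (avoids mask-edge artefacts); statistics are pooled over in-mask pixels
  for the same-geometry maps (Laws, LBP, Gabor) and over the whole
  transform plane for the decimated/frequency maps (wavelet, DOST).
  Run-length runs and co-occurrence pairs never cross the mask boundary.
* **Energy and entropy.** Energy is the mean of squared map values.
  Entropy is Shannon entropy, log base 2, of a 256-bin min-max histogram
  of the map (a constant map has entropy 0); the LBP family bins its
  integer codes directly into the 256 possible values.
* **Quantization.** Min-max onto `2^bit_depth` levels over the in-mask
  intensity range: 8-bit for the co-occurrence matrix, 16 levels for run
  lengths (256-level run matrices are uninformative on small ROIs); both
  configurable. A constant ROI quantizes to all zeros and is flagged.
* **Degenerate inputs.** Zero-variance skewness/kurtosis are 0;
  correlation-type co-occurrence features are 0 when a marginal SD is 0.

Family-specific choices:

* **Laws.** The 2D kernels are outer products of L5/E5/S5/R5; transposed
  pairs (e.g. L5E5 and E5L5) are averaged pixelwise *before* the energy
  and entropy operators (the alternative order is a one-line change).
  Convolution uses edge replication so the zero-sum kernels annihilate
  constant images exactly.
* **DOST.** The discrete orthonormal Stockwell transform is implemented as
  a unitary FFT band partition with dyadic bands {0}, {1}, {2-3}, ...,
  {N/2..N-1} per axis on the slice padded to dyadic size; any such
  partition is exactly orthonormal, and the suite asserts Parseval
  equality. The coefficient magnitude plane is cut into a 3 x 3 grid of
  near-equal blocks (energies then entropies, row-major).
* **Wavelets.** Six-level separable Daubechies-4 analysis with
  *periodized* extension, so the transform is exactly orthonormal and
  sub-band energies sum to the image energy to machine precision; slices
  are padded to at least 64 (2^6) so six levels always exist. Symmetric
  padding was considered and rejected because it breaks exact energy
  conservation, which is the family's main invariant test.
* **Gabor.** Five wavelengths {2, 4, 8, 16, 32} voxels by four
  orientations {0, 45, 90, 135} degrees, one-octave bandwidth, complex
  kernels with both quadratures DC-corrected so constant images give a
  zero response. Filtering is circular FFT convolution on a fixed 64-pixel
  grid — fixed so that a 15-pixel training ROI and a 25-pixel mapping
  window see the *same* effective filters.
* **LBP.** Radius-1, 8-neighbour codes (bit set when neighbour >= centre);
  features are energy, entropy, mean, SD, skewness, kurtosis of the code
  map. The published feature list for this family repeats "entropy"
  twice, which we read as a typo for energy + entropy.
* **GLCM.** Symmetric counts accumulated over the four in-plane unit
  offsets and all slices, normalised once; the 22 statistics follow the
  standard Haralick-family definitions (both correlation forms are
  mathematically identical and agree numerically, they are retained for
  the published 22-column layout).

## PLSC and its inference

The two observation matrices (rows = ROIs in identical order, columns =
168 features) are z-scored per column; zero-variance columns (deep
wavelet entropies on small ROIs are the usual case) become all-zero with
a warning. The SVD of `R = X'Y/(n-1)` gives saliences `U`, `V` and
singular values `d`; the 1/(n-1) scaling is a covariance convention —
any positive factor rescales `d` without changing saliences, latent
scores, ranks or p-values. Sign indeterminacy is fixed by making each U
column's largest-magnitude loading positive (flipping the paired V
column), so refits are bit-identical.

* **Permutation test.** Whole rows of Y are permuted (X fixed), which
  preserves each block's internal feature correlation and tests only the
  cross-block association; the empirical p is `(#{null >= obs} + 1)/(B+1)`.
  Because `sum(d^2) = ||R||_F^2`, each permutation needs only a
  cross-product, not an SVD — identical value, orders of magnitude
  faster at B = 10,000. Calibration under independent blocks is asserted
  by the test suite (type-I error within binomial bounds of 5%, p-values
  uniform).
* **Bootstrap ratios.** ROIs are resampled with replacement; each
  resample's decomposition is aligned to the original latent dimension by
  choosing the best-matching axis (absolute combined dot product,
  excluding axes with vanishing singular value) and flipping its sign to
  agree — without this, SVD sign/axis indeterminacy corrupts the ratios.
  The ratio is mean/SD of the resampled salience per feature;
  |ratio| > 2.00 is the significance rule (roughly a 95% t criterion).
  The target of the bootstrap is the feature saliences (the published
  ranking tables rank original features), recorded as an interpretation.
* **Selection.** Per latent variable, a pooled-variance one-way ANOVA of
  DIL vs NT scores with Holm correction across the tested variables
  within each modality block (the correction family is per modality and
  configurable), plus a mean-silhouette filter at 0.5. The first
  `k_per_modality` (default 4) surviving variables per block form the
  latent feature set — 8 values per ROI when four pass per modality. On
  the homogeneous synthetic cohorts a single latent dimension carries the
  implanted contrast, so typically one variable per block passes; the
  selection object simply carries fewer columns in that case.
* **Projection.** New feature rows are standardized with the *training*
  means/scales and multiplied by the saliences — used by cross-cohort
  evaluation, contour testing and mapping, so no test-time statistics
  leak into the model. Cross-validation refits nothing by default at
  projection time; the latent selection is computed once on the training
  cohort (the fit-once protocol), and subject-level folds keep each
  subject's DIL and NT rows together.

## The perceptron

Architecture 8:5:1 (input = latent features, one hidden layer, one
output), bipolar sigmoid `f(x) = 2/(1+e^{-x}) - 1 = tanh(x/2)` on hidden
and output, targets DIL = +1 / NT = -1, MSE loss. Training is strict
batch back-propagation: gradients are accumulated over the whole training
set and applied once per epoch with learning rate 0.01 and momentum 0.01;
the analytic gradient is verified against central finite differences.
Initial weights are uniform on [-0.5, 0.5] from a stored seed, and
leave-one-out cross-validation reuses the *same* initial weights in every
fold. Validation:

* **Strategy 1 (LOOCV).** One fold per subject (training fraction
  `1 - 1/K`); held-out scores are pooled into one ROC. The pooled
  correct-classification fraction (decision at score 0) per epoch gives
  the CCF curve; its normalised area (AUCCF) and AUROC drive the
  hidden-size search (ties favour the smaller network). The stopping
  epoch is the first epoch whose CCF comes within 10% of the plateau
  (mean CCF over the final 10% of epochs); "10% of the total rise" is
  the selectable alternative reading.
* **Strategy 2.** 100 random subject-stratified 67/33 splits; AUROC, PPV
  and NPV at each split's optimal cut-point, summarised by means with
  2.5/97.5 percentile intervals (the percentile method is our choice; the
  published analysis does not state one).
* **ROC conventions.** Thresholds at midpoints between consecutive unique
  scores (plus extremes), trapezoidal AUROC, optimal cut-point minimizing
  the Euclidean distance to (FPR, TPR) = (0, 1). Midpoints matter for
  transfer: with separable training scores the cut-point then sits midway
  between the classes instead of exactly on the smallest positive score.
* **Cross-cohort evaluation.** PLSC, standardization and the MLP are
  fitted on cohort A only; cohort B is projected and scored frozen, with
  sensitivity/specificity read at A's cut-point.

## Lesion probability maps and contour robustness

For each 25 x 25 window position (stride 1 by default; larger strides
trade resolution for speed), the full 168-feature vector is extracted
from each harmonized modality treating the whole window as the ROI,
projected through the frozen PLSC model onto the selected latent
variables, scored by the frozen MLP, and mapped to `(score + 1)/2`.
Windows are harmonized by the subject's NT-mask mean — the models expect
harmonized inputs, so the NT mask is a required input to mapping.
Thresholding assigns each covered voxel the probability of its nearest
window centre and keeps voxels above `p_thr`; the default 0.001 follows
the printed setting, which is extremely permissive — with a
well-calibrated map it selects nearly all covered voxels, so Dice against
the true lesion is dominated by the covered-area geometry unless a
stricter threshold (e.g. 0.5) is used. Dice is `2|A n B|/(|A|+|B|)`,
defined 1 for two empty masks.

The contour-variability test scales each contour by 1.2 about its
centroid (nearest-neighbour resampling) and shifts it by one voxel along
every axis — read as a single translation, with other modes selectable —
then repeats extraction and projection and compares original vs perturbed
per-subject DIL scores with a pooled-variance ANOVA per latent variable
against `Fc = qf(0.95, 1, 2n-2)` (4.11 for n = 19). On our synthetic
cohorts the F statistics far exceed Fc at the default perturbation: every
subject has an identical, sharp-edged lesion, so a 1.2x contour dilutes
each ROI with the same fraction of normal tissue and the within-group
variance in the denominator is tiny. The suite therefore verifies the
mechanism — F near 0 for identity contours, F growing monotonically with
perturbation severity, the critical value itself — rather than asserting
a pass that only heterogeneous, real cohorts (with large between-subject
variance) can be expected to show.

## Problem sizes and determinism

The reference scale used by the acceptance checks is the 117-subject
cohort (234 ROIs per modality), B = 10,000 permutations, 500 bootstrap
resamples and 150 training epochs; unit tests run the same code on 3-12
subject cohorts, B = 200, and toy latent tables, sizes chosen so the
whole suite exercises every path at desk scale. Every stochastic step
(cohort generation, permutations, resampling, weight initialisation,
splits) takes an explicit seed and is bit-reproducible; pipeline stages
record a config digest, seed and input hashes in their manifests.

## Known limitations

* All texture families are 2D per slice; no 3D variants and no
  morphological/shape features.
* The generator's homogeneity makes some population-level behaviours
  (contour-robustness pass rates, realistic CV variance) optimistic or
  pessimistic relative to real cohorts, as discussed above.
* Rician noise is available only as a Gaussian approximation toggle on
  the DWI signals.
* Dense (stride-1) probability maps are expensive in pure R; practical
  use maps selected slices or uses strides of 4-13.
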