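# radplsc

Discriminating dominant intra-prostatic lesions (DIL) from mirrored
contralateral normal prostatic tissue (NT) on paired T2-weighted and
apparent-diffusion-coefficient (ADC) MR volumes is a common building block
for focal-therapy planning: the lesion is hypo-intense and texturally
distinct on both modalities, and the two modalities carry correlated but
complementary information. `radplsc` implements that analysis end to end
for method development on synthetic imaging data:

1. **Synthetic paired-modality cohorts** — Gaussian-random-field textures
   with an implanted hypo-intense lesion, mirrored NT control masks,
   mono-exponential diffusion decay `S(b) = S0 exp(-b * ADC)` for DWI, and
   a null (`effect_size = 0`) setting in which DIL and NT are exchangeable.
2. **Radiomics** — ADC fitting by per-voxel log-linear regression over
   b-values, NT-mean intensity harmonization, and a 168-feature descriptor
   per ROI per modality in eight families: intensity histogram (9),
   gray-level run length (7), Laws kernels (18), discrete orthonormal
   Stockwell transform (18), local binary patterns (6), 2D wavelets (48),
   Gabor bank (40), gray-level co-occurrence (22).
3. **Partial least squares correlation (PLSC)** — the SVD of the
   cross-block covariance `R = X'Y/(n-1)` of the two standardized
   observation matrices yields salience pairs `(u_k, v_k)` and singular
   values `d_k`; latent scores are `Lx = X U`, `Ly = Y V` and the inertia
   `sum(d_k^2)` is the total cross-modality covariance. Inference:
   a permutation test of the inertia (rows of one block permuted), a
   bootstrap-ratio ranking of feature saliences (`|mean/sd| > 2.00`
   significant), per-latent ANOVA with Holm correction, and a silhouette
   filter (threshold 0.5) for discriminant latent variables.
4. **Classifier** — an 8:5:1 multilayer perceptron with bipolar-sigmoid
   activation `f(x) = 2/(1+e^{-x}) - 1`, batch back-propagation (learning
   rate 0.01, momentum 0.01), leave-one-subject-out cross-validation with
   shared initial weights, CCF/AUCCF stopping-epoch selection, repeated
   stratified 67/33 splits, ROC analytics with the closest-to-(0,1)
   optimal cut-point, and frozen-model cross-cohort evaluation.
5. **Lesion probability maps** — 25x25 sliding-window sampling of both
   harmonized modalities, projection through the frozen PLSC model, MLP
   scoring mapped to `[0, 1]`, thresholding into a DIL patch and Dice
   evaluation, plus a contour-robustness ANOVA against scaled/shifted
   contours (critical value `qf(0.95, 1, 2n-2)`).

## Worked example

```r
library(radplsc)

cohort   <- generate_cohort(cohort_config(n_subjects = 12, seed = 3))
features <- extract_features(cohort)          # 48 rows x 168 features
blocks   <- build_blocks(features)
fit      <- fit_plsc(blocks)

permutation_test_inertia(blocks, B = 200, seed = 9)
#> <plsc_permutation> observed inertia 3669, B = 200, p = 0.004975

anova_latent(fit, dimensions = 1:3) |> dplyr::filter(block == "ADC")
#> # A tibble: 3 x 6
#>   block dimension f_statistic  p_value   p_holm significant
#>   <chr>     <int>       <dbl>    <dbl>    <dbl> <lgl>
#> 1 ADC           1    548.     4.84e-17 3.88e-16 TRUE
#> 2 ADC           2      0.0114 9.16e- 1 1   e+ 0 FALSE
#> 3 ADC           3      0.0249 8.76e- 1 1   e+ 0 FALSE

sel <- select_discriminant(fit, anova_latent(fit, 1:8),
                           silhouette_filter(fit, 1:8))
cv  <- mlp_loocv(sel$features, n_hidden = 5,
                 config = mlp_train_config(max_epochs = 100))
cv
#> <mlp_cv> 12 folds (train fraction 0.92), AUROC 1.000, AUCCF 0.952
stopping_epoch(cv$ccf_curve)
#> [1] 11
```

The permutation p of ~0.005 (at B = 200) says the observed cross-modality
inertia was never reached under row permutation; the ANOVA shows only the
first ADC latent variable separates DIL from NT; the leave-one-out AUROC of
1.0 reflects the strong default lesion contrast (`effect_size = 2`).

The full pipeline (simulate → extract → plsc → train → evaluate → map →
variability) runs from one configuration:

```r
report <- run_pipeline(pipeline_config(seed = 42), out_dir = "out")
```

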