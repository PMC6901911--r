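# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# A small strong-effect cohort plus its fitted pipeline state, reused by the
# PLSC, MLP, lesion-map and pipeline tests.
small_pipeline <- function() {
  memo("small_pipeline", function() {
    cohort <- generate_cohort(cohort_config(n_subjects = 10, seed = 11))
    features <- extract_features(cohort)
    blocks <- suppressWarnings(build_blocks(features))
    model <- fit_plsc(blocks)
    av <- anova_latent(model, dimensions = 1:8)
    sil <- silhouette_filter(model, dimensions = 1:8)
    selection <- select_discriminant(model, av, sil, k_per_modality = 4)
    lm0 <- radplsc:::latent_matrix(selection$features)
    ann <- mlp_train(mlp_new(nrow(selection$selected), 5, seed = 1),
                     lm0$x, lm0$y, mlp_train_config(max_epochs = 100))
    list(cohort = cohort, features = features, blocks = blocks,
         model = model, anova = av, silhouette = sil,
         selection = selection, ann = ann)
  })
}

# Deterministic random ROI volume + ellipsoidal mask for fuzz tests.
random_roi <- function(seed, shape = c(4, 18, 18)) {
  withr::with_seed(seed, {
    vol <- array(rnorm(prod(shape), mean = 10), shape)
  })
  mask <- array(FALSE, shape)
  mask[2:(shape[1] - 1), 4:(shape[2] - 3), 4:(shape[3] - 3)] <- TRUE
  list(vol = vol, mask = mask)
}
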