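# End-to-end orchestration: simulate -> extract -> plsc -> train ->
# evaluate -> map -> variability, with YAML configuration, JSON manifests
# and per-stage artifacts. Stages persist their state under the output
# directory so later stages (or partial reruns) can resume.

#' Pipeline configuration
#'
#' Aggregates the settings of every stage. Stage seeds are derived from
#' `seed` (recorded in every manifest). `n_subjects_b` sizes the held-out
#' "group B" cohort used by the evaluate/map stages.
#'
#' @param cohort a [cohort_config()] for the training cohort (group A).
#' @param n_subjects_b held-out cohort size (default 19).
#' @param harmonize_adc apply NT-mean harmonization to ADC (default TRUE).
#' @param n_permutations permutation count for the inertia test.
#' @param n_boot bootstrap resamples for feature ranking.
#' @param alpha significance level for ANOVA/Holm.
#' @param silhouette_threshold minimum mean silhouette width.
#' @param k_per_modality latent variables kept per modality.
#' @param n_hidden hidden layer size of the MLP.
#' @param learning_rate,momentum,max_epochs MLP training settings.
#' @param n_split_iter repeated-split iterations (Strategy 2).
#' @param train_frac training fraction of the splits.
#' @param map_window,map_stride,p_thr probability-map settings.
#' @param n_map_subjects held-out subjects to map (default 2).
#' @param n_variability_subjects subjects in the contour test (default 19).
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            n_subjects_b = 19L,
                            harmonize_adc = TRUE,
                            n_permutations = 10000L,
                            n_boot = 500L,
                            alpha = 0.05,
                            silhouette_threshold = 0.5,
                            k_per_modality = 4L,
                            n_hidden = 5L,
                            learning_rate = 0.01,
                            momentum = 0.01,
                            max_epochs = 150L,
                            n_split_iter = 100L,
                            train_frac = 2 / 3,
                            map_window = 25L,
                            map_stride = 1L,
                            p_thr = 0.001,
                            n_map_subjects = 2L,
                            n_variability_subjects = 19L,
                            seed = 42L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys mirror the [pipeline_config()] arguments,
#'   with cohort settings nested under `cohort`.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_args <- y$cohort %||% list()
  y$cohort <- do.call(cohort_config, cohort_args)
  do.call(pipeline_config, y)
}

config_digest <- function(config) {
  digest::digest(unclass(config), algo = "sha256")
}

write_manifest <- function(dir, stage, config, inputs = character()) {
  manifest <- list(
    stage = stage,
    config_digest = config_digest(config),
    seed = config$seed,
    inputs = inputs,
    input_digests = vapply(inputs, function(p)
      if (file.exists(p)) digest::digest(file = p, algo = "sha256")
      else NA_character_, ""),
    package_version = as.character(utils::packageVersion("radplsc"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

stage_dir <- function(out_dir, stage) {
  d <- file.path(out_dir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

require_artifact <- function(path, producing_stage) {
  if (!file.exists(path))
    stop("missing artifact '", basename(path), "'; run stage '",
         producing_stage, "' first", call. = FALSE)
  path
}

mlp_config_of <- function(config) {
  mlp_train_config(learning_rate = config$learning_rate,
                   momentum = config$momentum,
                   max_epochs = config$max_epochs)
}

#' Run one pipeline stage
#'
#' Stages: `simulate`, `extract`, `plsc`, `train`, `evaluate`, `map`,
#' `variability`. Each writes its artifacts plus a JSON manifest (config
#' digest, seed, input hashes) under `out_dir/<stage>/` and an `.rds` state
#' file consumed by downstream stages. A missing upstream artifact raises
#' an error naming the stage to run.
#'
#' @param stage stage name.
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return the stage's result, invisibly.
#' @export
run_stage <- function(stage, config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  switch(stage,
    simulate = stage_simulate(config, out_dir),
    extract = stage_extract(config, out_dir),
    plsc = stage_plsc(config, out_dir),
    train = stage_train(config, out_dir),
    evaluate = stage_evaluate(config, out_dir),
    map = stage_map(config, out_dir),
    variability = stage_variability(config, out_dir),
    stop("unknown stage: ", stage))
}

stage_simulate <- function(config, out_dir) {
  d <- stage_dir(out_dir, "simulate")
  cohort_a <- generate_cohort(config$cohort)
  cfg_b <- config$cohort
  cfg_b$n_subjects <- as.integer(config$n_subjects_b)
  cfg_b$seed <- config$cohort$seed + 1L
  cfg_b$group_tag <- "B"
  cohort_b <- generate_cohort(cfg_b)
  write_cohort(cohort_a, file.path(d, "groupA"))
  write_cohort(cohort_b, file.path(d, "groupB"))
  saveRDS(list(cohort_a = cohort_a, cohort_b = cohort_b),
          file.path(d, "cohorts.rds"))
  write_manifest(d, "simulate", config)
  invisible(list(cohort_a = cohort_a, cohort_b = cohort_b))
}

load_stage <- function(out_dir, stage, file) {
  readRDS(require_artifact(file.path(out_dir, stage, file), stage))
}

stage_extract <- function(config, out_dir) {
  d <- stage_dir(out_dir, "extract")
  sim <- load_stage(out_dir, "simulate", "cohorts.rds")
  feats_a <- extract_features(sim$cohort_a,
                              harmonize_adc = config$harmonize_adc)
  feats_b <- extract_features(sim$cohort_b,
                              harmonize_adc = config$harmonize_adc)
  write.csv(feats_a, file.path(d, "features.csv"), row.names = FALSE)
  write.csv(feats_b, file.path(d, "features_groupB.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(harmonize_adc = config$harmonize_adc,
         n_features = 168L, feature_names = feature_names()),
    file.path(d, "extraction_settings.json"), auto_unbox = TRUE)
  saveRDS(list(feats_a = feats_a, feats_b = feats_b),
          file.path(d, "features.rds"))
  write_manifest(d, "extract", config,
                 file.path(out_dir, "simulate", "cohorts.rds"))
  invisible(list(feats_a = feats_a, feats_b = feats_b))
}

stage_plsc <- function(config, out_dir) {
  d <- stage_dir(out_dir, "plsc")
  feats <- load_stage(out_dir, "extract", "features.rds")
  blocks <- build_blocks(feats$feats_a)
  model <- fit_plsc(blocks)
  perm <- permutation_test_inertia(blocks, B = config$n_permutations,
                                   seed = config$seed)
  av <- anova_latent(model, dimensions = 1:8, alpha = config$alpha)
  sil <- silhouette_filter(model, dimensions = 1:8,
                           threshold = config$silhouette_threshold)
  selection <- select_discriminant(model, av, sil,
                                   k_per_modality = config$k_per_modality)
  ranking <- bootstrap_ratios(blocks, n_boot = config$n_boot,
                              seed = config$seed)
  write.csv(latent_scores(model, 1:8), file.path(d, "latent_scores.csv"),
            row.names = FALSE)
  write.csv(ranking, file.path(d, "ranking.csv"), row.names = FALSE)
  keep <- seq_len(max(8L, selection$selected$dimension %||% 8L))
  jsonlite::write_json(
    list(singular_values = model$d[keep],
         inertia = model$inertia,
         permutation_p = perm$p_value,
         center = model$center, scale = model$scale,
         saliences_t2w = model$U[, keep], saliences_adc = model$V[, keep],
         anova = av, silhouette = sil,
         selected = selection$selected),
    file.path(d, "plsc_model.json"), digits = NA)
  saveRDS(list(model = model, selection = selection, perm = perm,
               anova = av, silhouette = sil, ranking = ranking),
          file.path(d, "plsc.rds"))
  write_manifest(d, "plsc", config,
                 file.path(out_dir, "extract", "features.rds"))
  invisible(list(model = model, selection = selection, perm = perm,
                 anova = av, silhouette = sil, ranking = ranking))
}

stage_train <- function(config, out_dir) {
  d <- stage_dir(out_dir, "train")
  pl <- load_stage(out_dir, "plsc", "plsc.rds")
  if (nrow(pl$selection$selected) == 0)
    stop("empty latent selection; no discriminant variables to train on")
  tc <- mlp_config_of(config)
  cv <- mlp_loocv(pl$selection$features, n_hidden = config$n_hidden,
                  config = tc, seed = config$seed)
  stop_ep <- stopping_epoch(cv$ccf_curve)
  split_cv <- mlp_split_strategy(pl$selection$features,
                                 n_iter = config$n_split_iter,
                                 train_frac = config$train_frac,
                                 n_hidden = config$n_hidden,
                                 config = tc, seed = config$seed)
  lm0 <- latent_matrix(pl$selection$features)
  final <- mlp_train(mlp_new(ncol(lm0$x), config$n_hidden,
                             seed = config$seed),
                     lm0$x, lm0$y, tc)
  write.csv(split_cv$samples, file.path(d, "metrics.csv"), row.names = FALSE)
  write.csv(tidy(cv$roc), file.path(d, "roc_points.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(architecture = c(ncol(lm0$x), config$n_hidden, 1L),
         learning_rate = config$learning_rate, momentum = config$momentum,
         max_epochs = config$max_epochs, seed = config$seed,
         stopping_epoch = stop_ep,
         loocv_auroc = cv$roc$auroc, auccf = cv$auccf,
         W1 = final$W1, W2 = final$W2),
    file.path(d, "ann_model.json"), digits = NA)
  saveRDS(list(cv = cv, split_cv = split_cv, final = final,
               stopping_epoch = stop_ep),
          file.path(d, "train.rds"))
  write_manifest(d, "train", config, file.path(out_dir, "plsc", "plsc.rds"))
  invisible(list(cv = cv, split_cv = split_cv, final = final,
                 stopping_epoch = stop_ep))
}

stage_evaluate <- function(config, out_dir) {
  d <- stage_dir(out_dir, "evaluate")
  pl <- load_stage(out_dir, "plsc", "plsc.rds")
  feats <- load_stage(out_dir, "extract", "features.rds")
  lat_b <- project_selection(pl$model, pl$selection, feats$feats_b)
  cross <- mlp_cross_cohort(pl$selection$features, lat_b,
                            n_hidden = config$n_hidden,
                            config = mlp_config_of(config),
                            seed = config$seed)
  metrics <- tibble::tibble(
    cohort = "B", auroc = cross$test_roc$auroc,
    sensitivity = cross$sensitivity, specificity = cross$specificity,
    ppv = cross$test_roc$ppv, npv = cross$test_roc$npv,
    cutpoint = cross$cutpoint)
  write.csv(metrics, file.path(d, "cross_cohort_metrics.csv"),
            row.names = FALSE)
  saveRDS(list(cross = cross, lat_b = lat_b, metrics = metrics),
          file.path(d, "evaluate.rds"))
  write_manifest(d, "evaluate", config,
                 c(file.path(out_dir, "plsc", "plsc.rds"),
                   file.path(out_dir, "extract", "features.rds")))
  invisible(list(cross = cross, metrics = metrics))
}

stage_map <- function(config, out_dir) {
  d <- stage_dir(out_dir, "map")
  pl <- load_stage(out_dir, "plsc", "plsc.rds")
  tr <- load_stage(out_dir, "train", "train.rds")
  sim <- load_stage(out_dir, "simulate", "cohorts.rds")
  n_map <- min(config$n_map_subjects, length(sim$cohort_b))
  rows <- list()
  for (i in seq_len(n_map)) {
    s <- sim$cohort_b[[i]]
    mid_z <- round(dim(s$t2w_volume)[1] / 2)
    pm <- probability_map(s, pl$model, pl$selection, tr$final,
                          window = config$map_window,
                          stride = config$map_stride,
                          slices = mid_z,
                          harmonize_adc = config$harmonize_adc)
    patch <- threshold_map(pm, p_thr = config$p_thr)
    dz <- dice(patch[mid_z, , ], s$dil_mask[mid_z, , ])
    RNifti::writeNifti(RNifti::asNifti(patch * 1L),
                       file.path(d, paste0(s$subject_id, "_patch.nii.gz")))
    RNifti::writeNifti(RNifti::asNifti(probability_volume(pm)),
                       file.path(d, paste0(s$subject_id, "_pmap.nii.gz")))
    saveRDS(pm, file.path(d, paste0(s$subject_id, "_pmap.rds")))
    rows[[i]] <- tibble::tibble(subject_id = s$subject_id, slice = mid_z,
                                dice = dz)
  }
  report <- dplyr::bind_rows(rows)
  write.csv(report, file.path(d, "dice_report.csv"), row.names = FALSE)
  saveRDS(report, file.path(d, "map.rds"))
  write_manifest(d, "map", config,
                 c(file.path(out_dir, "plsc", "plsc.rds"),
                   file.path(out_dir, "train", "train.rds")))
  invisible(report)
}

stage_variability <- function(config, out_dir) {
  d <- stage_dir(out_dir, "variability")
  pl <- load_stage(out_dir, "plsc", "plsc.rds")
  sim <- load_stage(out_dir, "simulate", "cohorts.rds")
  n <- min(config$n_variability_subjects, length(sim$cohort_a))
  subset_ids <- withr::with_seed(config$seed,
                                 sample(seq_along(sim$cohort_a), n))
  vt <- contour_variability_test(sim$cohort_a[subset_ids], pl$model,
                                 pl$selection,
                                 alpha = config$alpha,
                                 harmonize_adc = config$harmonize_adc)
  write.csv(vt$results, file.path(d, "variability_report.csv"),
            row.names = FALSE)
  saveRDS(vt, file.path(d, "variability.rds"))
  write_manifest(d, "variability", config,
                 file.path(out_dir, "plsc", "plsc.rds"))
  invisible(vt)
}

#' Run the full pipeline
#'
#' Executes every stage in order and assembles a summary report.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory for all artifacts.
#' @param stages stages to run, in order.
#' @return list of class `pipeline_report`.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "extract", "plsc", "train",
                                    "evaluate", "map", "variability")) {
  results <- list()
  for (st in stages) {
    message("[radplsc] stage: ", st)
    if (st %in% c("train", "evaluate", "map", "variability") &&
        !is.null(results$plsc) &&
        nrow(results$plsc$selection$selected) == 0) {
      message("[radplsc] empty latent selection; skipping stage: ", st)
      next
    }
    results[[st]] <- run_stage(st, config, out_dir)
  }
  report <- list(
    config = config,
    selected = results$plsc$selection$selected,
    selection_empty = nrow(results$plsc$selection$selected %||%
                             data.frame()) == 0,
    permutation_p = results$plsc$perm$p_value,
    ranking_top = head(results$plsc$ranking, 10),
    loocv_auroc = results$train$cv$roc$auroc,
    stopping_epoch = results$train$stopping_epoch,
    split_summary = results$train$split_cv$summary,
    cross_cohort = results$evaluate$metrics,
    dice = results$map,
    variability = results$variability$results,
    results = results)
  class(report) <- "pipeline_report"
  jsonlite::write_json(
    report[c("permutation_p", "loocv_auroc", "stopping_epoch")],
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  if (isTRUE(x$selection_empty)) {
    cat("  latent selection: EMPTY (no discriminant variables)\n")
  } else {
    cat("  latent selection:",
        paste(sprintf("%s:%d", x$selected$block, x$selected$dimension),
              collapse = ", "), "\n")
    cat(sprintf("  permutation p = %.4g, LOOCV AUROC = %.3f, stop epoch = %d\n",
                x$permutation_p, x$loocv_auroc, x$stopping_epoch))
  }
  invisible(x)
}
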