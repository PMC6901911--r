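# PLSC inference: permutation inertia test, bootstrap-ratio feature
# ranking, per-latent ANOVA with Holm correction, silhouette filtering and
# discriminant latent-variable selection.

# Cross-block inertia without an SVD: sum(d^2) = ||X'Y/(n-1)||_F^2.
cross_inertia <- function(X, Y) {
  R <- crossprod(X, Y) / (nrow(X) - 1)
  sum(R^2)
}

#' Permutation test of the PLSC inertia
#'
#' Rows of the Y block are permuted `B` times (X fixed, preserving each
#' block's internal feature correlation); the inertia is recomputed for each
#' permutation and the empirical p-value is
#' `(# null >= observed + 1) / (B + 1)`.
#'
#' @param blocks output of [build_blocks()] (or list with matrices X, Y).
#' @param B number of permutations (the reference analysis uses 10,000).
#' @param seed RNG seed.
#' @param perms optional list of explicit row permutations (overrides `B`),
#'   mainly for testing.
#' @return object of class `plsc_permutation` with `observed`, `null`
#'   (length B) and `p_value`.
#' @export
permutation_test_inertia <- function(blocks, B = 10000L, seed = 1L,
                                     perms = NULL) {
  X <- blocks$X; Y <- blocks$Y
  if (is.null(perms) && B < 1) stop("B must be >= 1")
  n <- nrow(X)
  observed <- cross_inertia(X, Y)
  null_vals <- withr::with_seed(seed, {
    if (is.null(perms)) perms <- replicate(B, sample.int(n), simplify = FALSE)
    vapply(perms, function(p) cross_inertia(X, Y[p, , drop = FALSE]), 0)
  })
  B_eff <- length(null_vals)
  p <- (sum(null_vals >= observed) + 1) / (B_eff + 1)
  structure(list(observed = observed, null = null_vals, p_value = p,
                 B = B_eff),
            class = "plsc_permutation")
}

#' @export
print.plsc_permutation <- function(x, ...) {
  cat(sprintf("<plsc_permutation> observed inertia %.4g, B = %d, p = %.4g\n",
              x$observed, x$B, x$p_value))
  invisible(x)
}

#' Histogram of the permutation null with the observed inertia
#' @param object a `plsc_permutation`.
#' @param ... unused.
#' @method autoplot plsc_permutation
#' @export
autoplot.plsc_permutation <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(inertia = object$null),
                  ggplot2::aes(x = .data$inertia)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "null inertia", y = "count") +
    ggplot2::theme_minimal()
}

#' Bootstrap-ratio feature ranking
#'
#' Rows (ROIs) are resampled with replacement `n_boot` times; the PLSC is
#' refit on each resample and the salience column of the requested latent
#' dimension is aligned to the original fit (best-matching column by
#' absolute combined dot product, sign-flipped to agree). The bootstrap
#' ratio of a feature is the mean of its resampled salience divided by its
#' standard deviation; |ratio| > 2.00 is flagged significant (roughly a 95%
#' t-criterion). Zero-variance features get an infinite ratio and rank
#' first.
#'
#' @param blocks output of [build_blocks()].
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param seed RNG seed.
#' @param dimension latent dimension whose saliences are ranked.
#' @param threshold significance threshold on |ratio|.
#' @return tibble with columns `feature`, `modality`, `category`, `ratio`,
#'   `rank` (within modality), `significant`.
#' @export
bootstrap_ratios <- function(blocks, n_boot = 500L, seed = 1L,
                             dimension = 1L, threshold = 2.0) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  X <- blocks$X; Y <- blocks$Y
  n <- nrow(X)
  fit0 <- fit_plsc(blocks)
  u0 <- fit0$U[, dimension]; v0 <- fit0$V[, dimension]
  n_keep <- min(length(fit0$d), dimension + 3L)

  boot_u <- matrix(NA_real_, n_boot, nrow(fit0$U))
  boot_v <- matrix(NA_real_, n_boot, nrow(fit0$V))
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, replace = TRUE)
        if (length(unique(idx)) >= 3) break
      }
      Xb <- X[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      Rb <- crossprod(Xb, Yb) / (n - 1)
      svb <- svd(Rb, nu = n_keep, nv = n_keep)
      # axis + sign alignment to the original latent dimension; axes with
      # vanishing singular value are arbitrary and excluded from matching
      scores <- abs(crossprod(svb$u, u0) + crossprod(svb$v, v0))
      cand <- which(svb$d[seq_len(n_keep)] > svb$d[1] * 1e-8)
      if (length(cand) == 0) cand <- seq_len(n_keep)
      jbest <- cand[which.max(scores[cand])]
      s <- sign(sum(svb$u[, jbest] * u0) + sum(svb$v[, jbest] * v0))
      if (s == 0) s <- 1
      boot_u[b, ] <- s * svb$u[, jbest]
      boot_v[b, ] <- s * svb$v[, jbest]
    }
  })
  ratio_of <- function(m) {
    mu <- colMeans(m)
    sdv <- apply(m, 2, sd)
    # (numerically) zero bootstrap variance: infinite-ratio sentinel
    degenerate <- sdv <= abs(mu) * 1e-12
    ifelse(degenerate, ifelse(mu == 0, 0, Inf) * sign(mu), mu / sdv)
  }
  fn <- fit0$feature_names
  cats <- if (length(fn) == 168) feature_categories() else
    rep(NA_character_, length(fn))
  res <- dplyr::bind_rows(
    tibble::tibble(feature = fn, modality = "T2W", category = cats,
                   ratio = ratio_of(boot_u)),
    tibble::tibble(feature = fn, modality = "ADC", category = cats,
                   ratio = ratio_of(boot_v)))
  res <- dplyr::mutate(
    dplyr::group_by(res, .data$modality),
    rank = rank(-abs(.data$ratio), ties.method = "first"))
  res <- dplyr::ungroup(res)
  res$significant <- abs(res$ratio) > threshold
  dplyr::arrange(res, .data$modality, .data$rank)
}

#' Per-latent-variable ANOVA with Holm correction
#'
#' One-way fixed-effects ANOVA (homoscedastic, i.e. pooled variance) of each
#' latent variable's scores between the DIL and NT groups;
#' Holm-Bonferroni adjustment across the tested variables within each
#' modality block at the given alpha.
#'
#' @param model a `plsc_fit`.
#' @param dimensions latent dimensions to test (default: all fitted).
#' @param alpha familywise significance level.
#' @return tibble with `block`, `dimension`, `f_statistic`, `p_value`,
#'   `p_holm`, `significant`.
#' @export
anova_latent <- function(model, dimensions = seq_along(model$d),
                         alpha = 0.05) {
  groups <- factor(model$labels$roi)
  if (nlevels(groups) < 2) stop("need two groups (DIL and NT)")
  one <- function(scores) {
    ft <- oneway.test(scores ~ groups, var.equal = TRUE)
    c(f = unname(ft$statistic), p = unname(ft$p.value))
  }
  res <- dplyr::bind_rows(lapply(c("T2W", "ADC"), function(bl) {
    S <- if (bl == "T2W") model$Lx else model$Ly
    stats_mat <- t(vapply(dimensions, function(k) one(S[, k]), c(f = 0, p = 0)))
    tibble::tibble(block = bl, dimension = dimensions,
                   f_statistic = unname(stats_mat[, "f"]),
                   p_value = unname(stats_mat[, "p"]))
  }))
  res <- dplyr::mutate(dplyr::group_by(res, .data$block),
                       p_holm = p.adjust(.data$p_value, method = "holm"))
  res <- dplyr::ungroup(res)
  res$significant <- res$p_holm < alpha
  res
}

#' Silhouette filter on latent scores
#'
#' Mean silhouette width of the DIL/NT clustering of each latent variable
#' (Euclidean distance on the 1-D scores); a variable passes when the mean
#' width reaches the threshold. Singleton clusters have width 0.
#'
#' @param model a `plsc_fit`.
#' @param dimensions latent dimensions to test.
#' @param threshold minimum mean silhouette coefficient (default 0.5).
#' @return tibble with `block`, `dimension`, `silhouette`, `pass`.
#' @export
silhouette_filter <- function(model, dimensions = seq_along(model$d),
                              threshold = 0.5) {
  groups <- as.integer(factor(model$labels$roi))
  res <- dplyr::bind_rows(lapply(c("T2W", "ADC"), function(bl) {
    S <- if (bl == "T2W") model$Lx else model$Ly
    sil <- vapply(dimensions, function(k) {
      sw <- cluster::silhouette(groups, stats::dist(S[, k]))
      mean(sw[, "sil_width"])
    }, 0)
    tibble::tibble(block = bl, dimension = dimensions, silhouette = sil)
  }))
  res$pass <- res$silhouette >= threshold
  res
}

#' Select the discriminant latent variables and build the latent feature set
#'
#' Keeps latent variables that pass both the Holm-adjusted ANOVA and the
#' silhouette filter, takes the first `k_per_modality` per block, and
#' assembles the per-ROI latent feature table (by default 4 + 4 = 8 scores).
#'
#' @param model a `plsc_fit`.
#' @param anova result of [anova_latent()].
#' @param silhouette result of [silhouette_filter()]; `NULL` skips the
#'   silhouette criterion.
#' @param k_per_modality latent variables retained per modality block.
#' @return object of class `latent_selection`: list with `selected` (tibble
#'   of retained block/dimension pairs) and `features` (tibble with one row
#'   per ROI: labels plus `t2w_lv*` and `adc_lv*` score columns; empty
#'   selection gives a tibble with label columns only).
#' @export
select_discriminant <- function(model, anova, silhouette = NULL,
                                k_per_modality = 4L) {
  ok <- dplyr::filter(anova, .data$significant)
  if (!is.null(silhouette)) {
    ok <- dplyr::inner_join(ok,
      dplyr::filter(silhouette, .data$pass)[, c("block", "dimension")],
      by = c("block", "dimension"))
  }
  ok <- dplyr::slice_head(dplyr::group_by(dplyr::arrange(ok, .data$dimension),
                                          .data$block),
                          n = k_per_modality)
  ok <- dplyr::ungroup(ok)
  feats <- model$labels
  sel <- ok[, c("block", "dimension")]
  for (i in seq_len(nrow(sel))) {
    bl <- sel$block[i]; k <- sel$dimension[i]
    nm <- sprintf("%s_lv%d", tolower(bl), k)
    feats[[nm]] <- if (bl == "T2W") model$Lx[, k] else model$Ly[, k]
  }
  structure(list(selected = sel, features = feats,
                 k_per_modality = k_per_modality),
            class = "latent_selection")
}

#' @export
print.latent_selection <- function(x, ...) {
  if (nrow(x$selected) == 0) {
    cat("<latent_selection> empty selection (no discriminant latent variables)\n")
  } else {
    cat(sprintf("<latent_selection> %d latent variables: %s\n",
                nrow(x$selected),
                paste(sprintf("%s:%d", x$selected$block, x$selected$dimension),
                      collapse = ", ")))
  }
  invisible(x)
}

# Score matrix (ROIs x selected latents) and +-1 class labels from a
# latent_selection; DIL is coded +1, NT is -1.
selection_matrix <- function(selection) {
  feats <- selection$features
  score_cols <- setdiff(names(feats), c("subject_id", "roi", "group_tag"))
  if (length(score_cols) == 0) stop("empty latent selection")
  list(x = as.matrix(feats[, score_cols]),
       y = ifelse(feats$roi == "DIL", 1, -1),
       subject_id = feats$subject_id,
       score_cols = score_cols)
}

#' Project a feature table through a fitted model and selection
#'
#' Standardizes new feature rows with the training parameters, projects them
#' onto the selected latent dimensions and returns the latent feature table
#' aligned with [select_discriminant()] output.
#'
#' @param model a `plsc_fit` (fitted on the training cohort).
#' @param selection a `latent_selection` from the same model.
#' @param feature_table tibble from [extract_features()] for the new ROIs.
#' @return tibble with label columns and the selected latent score columns.
#' @export
project_selection <- function(model, selection, feature_table) {
  xs <- dplyr::arrange(dplyr::filter(feature_table, .data$modality == "T2W"),
                       .data$subject_id, .data$roi)
  ys <- dplyr::arrange(dplyr::filter(feature_table, .data$modality == "ADC"),
                       .data$subject_id, .data$roi)
  stopifnot(identical(paste(xs$subject_id, xs$roi),
                      paste(ys$subject_id, ys$roi)))
  Lx <- plsc_project(model, xs, "X")
  Ly <- plsc_project(model, ys, "Y")
  out <- tibble::tibble(subject_id = xs$subject_id, roi = xs$roi,
                        group_tag = xs$group_tag)
  sel <- selection$selected
  for (i in seq_len(nrow(sel))) {
    bl <- sel$block[i]; k <- sel$dimension[i]
    nm <- sprintf("%s_lv%d", tolower(bl), k)
    out[[nm]] <- if (bl == "T2W") Lx[, k] else Ly[, k]
  }
  out
}
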