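# Validation strategies for the latent-variable MLP: ROC analytics,
# leave-one-out cross-validation (subject-level folds), architecture and
# stopping-epoch selection, repeated stratified splits, and cross-cohort
# evaluation.

as_pm1 <- function(labels) {
  if (is.numeric(labels)) return(ifelse(labels > 0, 1, -1))
  ifelse(labels %in% c("DIL", "1", "+1", "pos", "TRUE"), 1, -1)
}

#' ROC analysis of classifier scores
#'
#' Threshold sweep over the unique scores (prediction positive when
#' score >= threshold), trapezoidal AUROC, the optimal cut-point minimizing
#' the Euclidean distance of (FPR, TPR) to the (0, 1) corner, PPV/NPV at the
#' cut-point, and the correct-classification fraction CCF = (TP + TN)/n per
#' threshold.
#'
#' @param scores numeric classifier outputs.
#' @param labels class labels; `"DIL"`/positive numbers are positive.
#' @return object of class `roc_analysis` with the sweep tibble (`curve`),
#'   `auroc`, `cutpoint`, and `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `ccf` at the cut-point.
#' @export
roc_analysis <- function(scores, labels) {
  y <- as_pm1(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  np <- sum(y > 0); nn <- sum(y < 0)
  u <- sort(unique(scores))
  # thresholds at midpoints between consecutive unique scores (plus the
  # extremes), so a separable cut-point sits midway between the classes
  thr <- if (length(u) == 1) u else c(u[1] - 1, (head(u, -1) + tail(u, -1)) / 2)
  sweep_tb <- dplyr::bind_rows(lapply(c(thr, u[length(u)] + 1), function(t) {
    pos <- scores >= t
    tp <- sum(pos & y > 0); fp <- sum(pos & y < 0)
    tibble::tibble(threshold = t, tpr = tp / np, fpr = fp / nn,
                   ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                   npv = if (sum(!pos) > 0) sum(!pos & y < 0) / sum(!pos)
                         else NA_real_,
                   ccf = (tp + (nn - fp)) / (np + nn))
  }))
  ord <- order(sweep_tb$fpr, sweep_tb$tpr)
  auroc <- sum(diff(sweep_tb$fpr[ord]) *
               (head(sweep_tb$tpr[ord], -1) + tail(sweep_tb$tpr[ord], -1)) / 2)
  finite <- is.finite(sweep_tb$threshold)
  dist <- sqrt(sweep_tb$fpr^2 + (1 - sweep_tb$tpr)^2)
  best <- which(finite)[which.min(dist[finite])]
  structure(
    list(curve = sweep_tb, auroc = auroc,
         cutpoint = sweep_tb$threshold[best],
         distance = dist[best],
         sensitivity = sweep_tb$tpr[best],
         specificity = 1 - sweep_tb$fpr[best],
         ppv = sweep_tb$ppv[best], npv = sweep_tb$npv[best],
         ccf = sweep_tb$ccf[best]),
    class = "roc_analysis")
}

#' @export
print.roc_analysis <- function(x, ...) {
  cat(sprintf(
    "<roc_analysis> AUROC %.3f, cut-point %.3f (sens %.3f, spec %.3f, PPV %.3f, NPV %.3f)\n",
    x$auroc, x$cutpoint, x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

#' Tidy the ROC sweep
#' @param x a `roc_analysis`.
#' @param ... unused.
#' @method tidy roc_analysis
#' @export
tidy.roc_analysis <- function(x, ...) x$curve

#' @method glance roc_analysis
#' @export
glance.roc_analysis <- function(x, ...) {
  tibble::tibble(auroc = x$auroc, cutpoint = x$cutpoint,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 ppv = x$ppv, npv = x$npv, ccf = x$ccf)
}

#' ROC curve plot
#' @param object a `roc_analysis`.
#' @param ... unused.
#' @method autoplot roc_analysis
#' @export
autoplot.roc_analysis <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 3) +
    ggplot2::annotate("point", x = 1 - object$specificity,
                      y = object$sensitivity, colour = "red") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUROC = %.3f", object$auroc)) +
    ggplot2::theme_minimal()
}

latent_matrix <- function(features) {
  score_cols <- setdiff(names(features), c("subject_id", "roi", "group_tag"))
  if (length(score_cols) == 0) stop("no latent score columns in features")
  list(x = as.matrix(features[, score_cols]),
       y = ifelse(features$roi == "DIL", 1, -1),
       subject_id = features$subject_id, score_cols = score_cols)
}

#' Leave-one-out cross-validation of the MLP (Strategy 1)
#'
#' One fold per subject: the held-out subject's DIL and NT rows leave
#' together, the network is retrained from the same stored initial weights
#' on the remaining subjects, and the held-out scores are pooled across
#' folds into one ROC. The pooled CCF-versus-epoch curve (decision at score
#' 0) and its normalised area (AUCCF) support stopping-epoch and
#' architecture selection.
#'
#' @param features latent feature tibble (from
#'   [select_discriminant()]`$features` or [project_selection()]).
#' @param n_hidden hidden-layer size.
#' @param config an [mlp_train_config()].
#' @param seed weight-initialization seed (same initial weights every fold).
#' @return object of class `mlp_cv` with pooled `predictions`, `roc`,
#'   `ccf_curve`, `auccf`, `train_fraction`, `n_folds`.
#' @export
mlp_loocv <- function(features, n_hidden = 5L, config = mlp_train_config(),
                      seed = 1L) {
  lm0 <- latent_matrix(features)
  subjects <- unique(lm0$subject_id)
  K <- length(subjects)
  if (K < 3) stop("LOOCV needs at least 3 subjects")
  init <- mlp_new(ncol(lm0$x), n_hidden, seed = seed)
  per_epoch <- matrix(NA_real_, config$max_epochs, nrow(lm0$x))
  final_scores <- numeric(nrow(lm0$x))
  for (s in subjects) {
    test_idx <- which(lm0$subject_id == s)
    train_idx <- setdiff(seq_len(nrow(lm0$x)), test_idx)
    xt <- lm0$x[test_idx, , drop = FALSE]
    trained <- mlp_train(init, lm0$x[train_idx, , drop = FALSE],
                         lm0$y[train_idx], config,
                         monitor = function(ep, m) mlp_forward(m, xt))
    for (ep in seq_len(config$max_epochs))
      per_epoch[ep, test_idx] <- trained$monitor[[ep]]
    final_scores[test_idx] <- trained$monitor[[config$max_epochs]]
  }
  ccf_curve <- apply(per_epoch, 1, function(sc)
    mean((sc >= 0) == (lm0$y > 0)))
  structure(
    list(predictions = tibble::tibble(subject_id = lm0$subject_id,
                                      roi = ifelse(lm0$y > 0, "DIL", "NT"),
                                      label = lm0$y, score = final_scores),
         roc = roc_analysis(final_scores, lm0$y),
         ccf_curve = ccf_curve, auccf = mean(ccf_curve),
         train_fraction = 1 - 1 / K, n_folds = K,
         n_hidden = n_hidden, seed = seed, config = config),
    class = "mlp_cv")
}

#' @export
print.mlp_cv <- function(x, ...) {
  cat(sprintf("<mlp_cv> %d folds (train fraction %.2f), AUROC %.3f, AUCCF %.3f\n",
              x$n_folds, x$train_fraction, x$roc$auroc, x$auccf))
  invisible(x)
}

#' Search the hidden-layer size by LOOCV performance
#'
#' @param features latent feature tibble.
#' @param hidden_range candidate hidden sizes.
#' @param config an [mlp_train_config()].
#' @param seed initialization seed shared across candidates.
#' @return list with `chosen` (the H maximizing pooled AUROC; ties favour
#'   the smaller network) and `results` (per-H tibble with AUROC and AUCCF).
#' @export
architecture_search <- function(features, hidden_range = 1:10,
                                config = mlp_train_config(), seed = 1L) {
  stopifnot(length(hidden_range) >= 1)
  rows <- lapply(hidden_range, function(H) {
    cv <- mlp_loocv(features, n_hidden = H, config = config, seed = seed)
    tibble::tibble(n_hidden = H, auroc = cv$roc$auroc, auccf = cv$auccf)
  })
  results <- dplyr::bind_rows(rows)
  best <- results$n_hidden[order(-results$auroc, results$n_hidden)][1]
  list(chosen = best, results = results)
}

#' Stopping epoch from a CCF-versus-epoch curve
#'
#' The plateau is the mean CCF over the final `tail_fraction` of epochs; the
#' stopping epoch is the first epoch whose CCF comes within
#' `plateau_fraction` of the plateau. `mode = "of_plateau"` measures the
#' margin as a fraction of the plateau value; `mode = "of_rise"` as a
#' fraction of the total rise from the first epoch.
#'
#' @param ccf_curve numeric CCF per epoch (length >= 2).
#' @param plateau_fraction allowed shortfall (default 0.10).
#' @param tail_fraction fraction of final epochs defining the plateau.
#' @param mode interpretation of the 10% margin.
#' @return integer epoch.
#' @export
stopping_epoch <- function(ccf_curve, plateau_fraction = 0.10,
                           tail_fraction = 0.10,
                           mode = c("of_plateau", "of_rise")) {
  mode <- match.arg(mode)
  stopifnot(length(ccf_curve) >= 2)
  n <- length(ccf_curve)
  tail_n <- max(1L, ceiling(tail_fraction * n))
  plateau <- mean(tail(ccf_curve, tail_n))
  if (!is.finite(plateau)) {
    warning("plateau undefined; returning final epoch")
    return(n)
  }
  cut <- if (mode == "of_plateau") plateau * (1 - plateau_fraction)
         else plateau - plateau_fraction * (plateau - ccf_curve[1])
  hit <- which(ccf_curve >= cut)
  if (length(hit) == 0) {
    warning("CCF never reaches the plateau band; returning final epoch")
    return(n)
  }
  hit[1]
}

#' Repeated stratified-split validation of the MLP (Strategy 2)
#'
#' `n_iter` independent splits sample `train_frac` of the subjects (both
#' their DIL and NT rows) for training and evaluate AUROC, PPV and NPV at
#' the split's optimal cut-point on the held-out rows; means and 2.5/97.5
#' percentile confidence intervals are reported.
#'
#' @param features latent feature tibble.
#' @param n_iter number of random splits (default 100).
#' @param train_frac fraction of subjects used for training (default 2/3).
#' @param n_hidden hidden-layer size.
#' @param config an [mlp_train_config()].
#' @param seed RNG seed for the splits and initial weights.
#' @return object of class `mlp_split_cv` with per-iteration `samples` and
#'   a `summary` tibble (mean and percentile CI per metric).
#' @export
mlp_split_strategy <- function(features, n_iter = 100L, train_frac = 2 / 3,
                               n_hidden = 5L, config = mlp_train_config(),
                               seed = 1L) {
  lm0 <- latent_matrix(features)
  subjects <- unique(lm0$subject_id)
  n_train <- round(train_frac * length(subjects))
  stopifnot(n_train >= 2, n_train < length(subjects))
  init <- mlp_new(ncol(lm0$x), n_hidden, seed = seed)
  rows <- withr::with_seed(seed, {
    lapply(seq_len(n_iter), function(it) {
      tr_sub <- sample(subjects, n_train)
      tr <- lm0$subject_id %in% tr_sub
      trained <- mlp_train(init, lm0$x[tr, , drop = FALSE], lm0$y[tr], config)
      roc <- roc_analysis(mlp_forward(trained, lm0$x[!tr, , drop = FALSE]),
                          lm0$y[!tr])
      tibble::tibble(iteration = it, auroc = roc$auroc, ppv = roc$ppv,
                     npv = roc$npv, sensitivity = roc$sensitivity,
                     specificity = roc$specificity)
    })
  })
  samples <- dplyr::bind_rows(rows)
  summary_tb <- tidyr::pivot_longer(samples, -"iteration",
                                    names_to = "metric")
  summary_tb <- dplyr::summarise(
    dplyr::group_by(summary_tb, .data$metric),
    mean = mean(.data$value, na.rm = TRUE),
    ci_lo = quantile(.data$value, 0.025, na.rm = TRUE, names = FALSE),
    ci_hi = quantile(.data$value, 0.975, na.rm = TRUE, names = FALSE),
    .groups = "drop")
  structure(list(samples = samples, summary = summary_tb,
                 n_iter = n_iter, train_frac = train_frac,
                 n_hidden = n_hidden, seed = seed),
            class = "mlp_split_cv")
}

#' @export
print.mlp_split_cv <- function(x, ...) {
  au <- x$summary[x$summary$metric == "auroc", ]
  cat(sprintf("<mlp_split_cv> %d splits, AUROC mean %.3f [%.3f, %.3f]\n",
              x$n_iter, au$mean, au$ci_lo, au$ci_hi))
  invisible(x)
}

#' Train on one cohort, evaluate on another (harmonization test)
#'
#' The network is trained on the training cohort's latent features; its
#' optimal cut-point is determined on the training ROC and then applied
#' unchanged to the test cohort, giving the unseen-cohort sensitivity,
#' specificity and ROC.
#'
#' @param train_features,test_features latent feature tibbles for the two
#'   cohorts; subject identifiers must be disjoint.
#' @param n_hidden hidden-layer size.
#' @param config an [mlp_train_config()].
#' @param seed initialization seed.
#' @return list with `train_roc`, `test_roc`, `cutpoint`, `sensitivity`,
#'   `specificity` (on the test cohort at the training cut-point) and the
#'   trained `model`.
#' @export
mlp_cross_cohort <- function(train_features, test_features, n_hidden = 5L,
                             config = mlp_train_config(), seed = 1L) {
  if (length(intersect(unique(train_features$subject_id),
                       unique(test_features$subject_id))) > 0)
    stop("training and test cohorts overlap")
  tr <- latent_matrix(train_features)
  te <- latent_matrix(test_features)
  stopifnot(identical(tr$score_cols, te$score_cols))
  trained <- mlp_train(mlp_new(ncol(tr$x), n_hidden, seed = seed),
                       tr$x, tr$y, config)
  train_roc <- roc_analysis(mlp_forward(trained, tr$x), tr$y)
  test_scores <- mlp_forward(trained, te$x)
  test_roc <- roc_analysis(test_scores, te$y)
  pos <- test_scores >= train_roc$cutpoint
  sens <- sum(pos & te$y > 0) / sum(te$y > 0)
  spec <- sum(!pos & te$y < 0) / sum(te$y < 0)
  list(train_roc = train_roc, test_roc = test_roc,
       cutpoint = train_roc$cutpoint,
       sensitivity = sens, specificity = spec, model = trained)
}
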