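# Small synthetic feature tables and raw blocks for PLSC unit tests.

toy_blocks <- function(n = 20, p = 5, q = 6, seed = 1, coupled = FALSE) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    Y <- if (coupled) X[, rep(seq_len(p), length.out = q)] +
           0.1 * matrix(rnorm(n * q), n, q)
         else matrix(rnorm(n * q), n, q)
  })
  list(X = scale(X)[, , drop = FALSE], Y = scale(Y)[, , drop = FALSE],
       labels = tibble::tibble(
         subject_id = sprintf("s%02d", rep(seq_len(n / 2), each = 2)),
         roi = rep(c("DIL", "NT"), n / 2),
         group_tag = "A"),
       center = list(X = rep(0, p), Y = rep(0, q)),
       scale = list(X = rep(1, p), Y = rep(1, q)),
       feature_names = NULL)
}

test_that("blocks are standardized, aligned and warn on constant columns", {
  pl <- small_pipeline()
  bl <- pl$blocks
  keep <- apply(bl$X, 2, sd) > 0
  expect_equal(unname(colMeans(bl$X)), rep(0, ncol(bl$X)), tolerance = 1e-8)
  expect_equal(unname(apply(bl$X[, keep], 2, sd)),
               rep(1, sum(keep)), tolerance = 1e-8)
  expect_identical(paste(bl$labels$subject_id, bl$labels$roi),
                   paste(rep(sapply(pl$cohort, `[[`, "subject_id"), each = 2),
                         rep(c("DIL", "NT"), length(pl$cohort))))
  # shuffling the feature table leaves the blocks identical (labels travel)
  shuffled <- pl$features[sample(nrow(pl$features)), ]
  bl2 <- suppressWarnings(build_blocks(shuffled))
  expect_equal(bl2$X, bl$X)
  expect_identical(bl2$labels, bl$labels)
  # constant column triggers the zero-variance convention
  ft <- pl$features
  ft$ibhf_mean <- 1
  expect_warning(expect_warning(b3 <- build_blocks(ft), "zero-variance"),
                 "zero-variance")
  expect_equal(unname(b3$X[, 1]), rep(0, nrow(b3$X)))
  # missing modality is an error
  expect_error(build_blocks(ft[ft$modality == "T2W", ]), "both modalities")
})

test_that("the symmetric case reduces to an eigendecomposition", {
  bl <- toy_blocks(16, 4, 4, seed = 2)
  bl$Y <- bl$X
  fit <- fit_plsc(bl)
  ev <- eigen(crossprod(bl$X) / (nrow(bl$X) - 1), symmetric = TRUE)
  expect_equal(fit$d, ev$values, tolerance = 1e-10)
  expect_equal(abs(fit$U), abs(fit$V), tolerance = 1e-10)
})

test_that("singular values match an independent eigen-based oracle", {
  bl <- toy_blocks(12, 3, 4, seed = 3, coupled = TRUE)
  fit <- fit_plsc(bl)
  R <- crossprod(bl$X, bl$Y) / (nrow(bl$X) - 1)
  oracle_d <- sqrt(pmax(eigen(crossprod(R), symmetric = TRUE)$values, 0))
  expect_equal(fit$d, oracle_d[seq_along(fit$d)], tolerance = 1e-10)
  # orthonormality and the inertia identity
  expect_lt(max(abs(crossprod(fit$U) - diag(ncol(fit$U)))), 1e-8)
  expect_lt(max(abs(crossprod(fit$V) - diag(ncol(fit$V)))), 1e-8)
  expect_equal(fit$inertia, sum(R^2), tolerance = 1e-10)
  expect_true(all(diff(fit$d) <= 1e-12))
  # covariance of paired latent scores is proportional to d
  for (k in 1:2) {
    expect_equal(sum(fit$Lx[, k] * fit$Ly[, k]) / (nrow(bl$X) - 1),
                 fit$d[k], tolerance = 1e-10)
  }
})

test_that("the sign convention makes refits deterministic", {
  bl <- toy_blocks(14, 4, 5, seed = 4, coupled = TRUE)
  f1 <- fit_plsc(bl); f2 <- fit_plsc(bl)
  expect_identical(f1$U, f2$U)
  for (k in seq_along(f1$d)) {
    expect_gte(f1$U[which.max(abs(f1$U[, k])), k], 0)
  }
})

test_that("projection reproduces training scores and checks dimensions", {
  pl <- small_pipeline()
  fit <- pl$model
  xs <- dplyr::arrange(
    dplyr::filter(pl$features, .data$modality == "T2W"),
    .data$subject_id, .data$roi)
  proj <- plsc_project(fit, xs, "X")
  expect_equal(unname(proj), unname(fit$Lx), tolerance = 1e-8)
  # an all-zero standardized vector scores zero
  z <- fit$center$X
  expect_equal(as.numeric(plsc_project(fit, matrix(z, 1), "X")),
               rep(0, length(fit$d)), tolerance = 1e-8)
  expect_error(plsc_project(fit, matrix(0, 1, 10), "X"), "mismatch")
})

test_that("identity permutations give p = 1 and the p-value formula holds", {
  bl <- toy_blocks(10, 3, 3, seed = 5)
  n <- nrow(bl$X)
  res <- permutation_test_inertia(bl, perms = list(seq_len(n), seq_len(n)))
  expect_equal(res$p_value, 1)
  expect_equal(res$observed, radplsc:::cross_inertia(bl$X, bl$Y))
  res2 <- permutation_test_inertia(bl, B = 50, seed = 2)
  expect_equal(res2$p_value,
               (sum(res2$null >= res2$observed) + 1) / 51)
  expect_error(permutation_test_inertia(bl, B = 0), "B must be")
})

test_that("the permutation test is calibrated under independence", {
  n_rep <- 200; B <- 200
  pvals <- vapply(seq_len(n_rep), function(r) {
    bl <- toy_blocks(20, 5, 5, seed = 6000 + r)
    permutation_test_inertia(bl, B = B, seed = r)$p_value
  }, 0)
  rej <- sum(pvals < 0.05)
  # Binomial(200, 0.05): central 99.9% range is about [2, 19]
  expect_gte(rej, 1)
  expect_lte(rej, 21)
  # and the null p-values are roughly uniform
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("ANOVA on latent scores matches the t-test identity", {
  pl <- small_pipeline()
  av <- anova_latent(pl$model, dimensions = 1:4)
  expect_true(all(av$f_statistic >= 0))
  expect_true(all(av$p_value >= 0 & av$p_value <= 1))
  # F equals the square of the pooled-variance t statistic
  sc <- pl$model$Lx[, 1]
  grp <- pl$model$labels$roi
  tt <- t.test(sc[grp == "DIL"], sc[grp == "NT"], var.equal = TRUE)
  expect_equal(av$f_statistic[av$block == "T2W" & av$dimension == 1],
               unname(tt$statistic)^2, tolerance = 1e-10)
  # equal group means give F = 0 (both groups see the values {1, 2})
  fake <- pl$model
  fake$Lx[, 2] <- rep(c(1, 1, 2, 2), length.out = nrow(fake$Lx))
  fake$Ly[, 2] <- fake$Lx[, 2]
  fake$labels$roi <- rep(c("DIL", "NT"), length.out = nrow(fake$Lx))
  av0 <- anova_latent(fake, dimensions = 2)
  expect_equal(av0$f_statistic, rep(0, 2), tolerance = 1e-12)
})

test_that("Holm correction follows the step-down procedure", {
  # direct check of the adjustment wiring on a fabricated score set
  p_raw <- c(0.001, 0.02, 0.04)
  holm <- p.adjust(p_raw, method = "holm")
  expect_equal(holm, c(0.003, 0.04, 0.04))
  expect_true(all(holm < 0.05))   # all three rejected at alpha = 0.05
})

test_that("the silhouette filter separates tight and interleaved clusters", {
  make_fit <- function(scores1) {
    n <- length(scores1)
    structure(list(
      Lx = cbind(scores1), Ly = cbind(scores1),
      d = 1,
      labels = tibble::tibble(
        subject_id = sprintf("s%d", seq_len(n)),
        roi = rep(c("DIL", "NT"), each = n / 2), group_tag = "A")),
      class = "plsc_fit")
  }
  far <- make_fit(c(rnorm(10, 0, 0.01), rnorm(10, 100, 0.01)))
  res_far <- silhouette_filter(far, dimensions = 1)
  expect_true(all(res_far$pass))
  expect_gt(min(res_far$silhouette), 0.99)
  inter <- make_fit(rep(c(0, 1), 10))
  res_int <- silhouette_filter(inter, dimensions = 1)
  expect_false(any(res_int$pass))
  # hand-computed 6-point set: DIL {0, 1, 2}, NT {10, 11, 12}
  hand <- make_fit(c(0, 1, 2, 10, 11, 12))
  res_hand <- silhouette_filter(hand, dimensions = 1)
  sw <- cluster::silhouette(rep(1:2, each = 3), dist(c(0, 1, 2, 10, 11, 12)))
  expect_equal(res_hand$silhouette[1], mean(sw[, 3]), tolerance = 1e-12)
})

test_that("discriminant selection assembles the latent feature set", {
  pl <- small_pipeline()
  sel <- pl$selection
  expect_gte(nrow(sel$selected), 2)   # both modalities separate strongly
  score_cols <- setdiff(names(sel$features),
                        c("subject_id", "roi", "group_tag"))
  expect_equal(length(score_cols), nrow(sel$selected))
  # k_per_modality = 4 with four passing dims per block gives 8 columns
  fake_av <- tibble::tibble(
    block = rep(c("T2W", "ADC"), each = 8), dimension = rep(1:8, 2),
    f_statistic = 10, p_value = 1e-6, p_holm = 1e-5, significant = TRUE)
  sel8 <- select_discriminant(pl$model, fake_av, NULL, k_per_modality = 4)
  expect_equal(nrow(sel8$selected), 8)
  expect_equal(ncol(sel8$features), 3 + 8)
  # nothing significant gives an explicit empty selection
  fake_av$significant <- FALSE
  sel0 <- select_discriminant(pl$model, fake_av, NULL)
  expect_equal(nrow(sel0$selected), 0)
  expect_output(print(sel0), "empty")
})

test_that("bootstrap ratios rank a planted feature first", {
  n <- 60
  withr::with_seed(9, {
    grp <- rep(c(1, -1), n / 2)
    X <- matrix(rnorm(n * 6), n, 6)
    Y <- matrix(rnorm(n * 6), n, 6)
    X[, 3] <- grp + 0.3 * rnorm(n)
    Y[, 3] <- grp + 0.3 * rnorm(n)
  })
  bl <- list(X = scale(X), Y = scale(Y),
             labels = tibble::tibble(subject_id = sprintf("s%d", 1:n),
                                     roi = ifelse(grp > 0, "DIL", "NT"),
                                     group_tag = "A"),
             center = list(X = rep(0, 6), Y = rep(0, 6)),
             scale = list(X = rep(1, 6), Y = rep(1, 6)),
             feature_names = NULL)
  rk <- bootstrap_ratios(bl, n_boot = 200, seed = 1)
  top <- dplyr::filter(rk, .data$rank == 1)
  expect_setequal(top$feature, "f3")
  expect_true(all(abs(top$ratio) > 2))
})

test_that("bootstrap significance is near nominal under pure noise", {
  flagged <- 0; total <- 0
  for (r in 1:6) {
    bl <- toy_blocks(40, 8, 8, seed = 300 + r)
    rk <- bootstrap_ratios(bl, n_boot = 150, seed = r)
    flagged <- flagged + sum(rk$significant)
    total <- total + nrow(rk)
  }
  rate <- flagged / total
  expect_lt(rate, 0.2)
})

test_that("a deterministic salience yields an infinite ratio ranked first", {
  n <- 12
  X <- cbind(rnorm(n), 0, 0)
  Y <- matrix(rnorm(n * 3), n, 3)
  bl <- list(X = X, Y = scale(Y),
             labels = tibble::tibble(subject_id = sprintf("s%d", 1:n),
                                     roi = rep(c("DIL", "NT"), 6),
                                     group_tag = "A"),
             center = list(X = rep(0, 3), Y = rep(0, 3)),
             scale = list(X = rep(1, 3), Y = rep(1, 3)),
             feature_names = NULL)
  rk <- bootstrap_ratios(bl, n_boot = 100, seed = 2)
  t2w <- dplyr::filter(rk, .data$modality == "T2W")
  expect_true(is.infinite(t2w$ratio[t2w$feature == "f1"]))
  expect_equal(t2w$rank[t2w$feature == "f1"], 1)
})

test_that("tidiers and glance return well-formed tibbles", {
  pl <- small_pipeline()
  td <- tidy(pl$model)
  expect_equal(nrow(td), 2 * 168 * length(pl$model$d))
  gl <- glance(pl$model)
  expect_equal(gl$n_features, 168)
  expect_s3_class(autoplot(pl$model), "ggplot")
  ls <- latent_scores(pl$model, 1:2)
  expect_equal(nrow(ls), 2 * 2 * nrow(pl$model$Lx))
})
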