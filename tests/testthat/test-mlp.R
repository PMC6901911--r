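# Toy 8-dimensional two-cluster data for classifier tests.
toy_latents <- function(n_subj = 12, sep = 4, seed = 1, p = 8) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_subj), function(i) {
      tibble::tibble(
        subject_id = sprintf("s%02d", i),
        roi = c("DIL", "NT"),
        group_tag = "A",
        !!!setNames(as.list(as.data.frame(
          matrix(rnorm(2 * p), 2, p) +
            outer(c(sep / 2, -sep / 2), rep(1, p)))),
          paste0("lv", seq_len(p))))
    })
  })
  dplyr::bind_rows(rows)
}

test_that("the forward pass matches a hand-rolled computation", {
  m <- mlp_new(8, 5, seed = 3)
  expect_equal(mlp_forward(m, rep(0, 8)),
               as.numeric(2 / (1 + exp(-(2 / (1 + exp(-m$W1[, 9])) - 1) %*%
                                         m$W2[1, 1:5] - m$W2[1, 6])) - 1),
               tolerance = 1e-12)
  withr::with_seed(4, x <- rnorm(8))
  f <- function(z) 2 / (1 + exp(-z)) - 1
  oracle <- f(sum(f(m$W1 %*% c(x, 1)) * m$W2[1, 1:5]) + m$W2[1, 6])
  expect_equal(mlp_forward(m, x), oracle, tolerance = 1e-12)
  # zero weights give the activation midpoint
  m0 <- m; m0$W1[] <- 0; m0$W2[] <- 0
  expect_equal(mlp_forward(m0, x), 0)
  expect_error(mlp_forward(m, rep(0, 5)), "n_input")
})

test_that("the bipolar sigmoid saturates at plus/minus one", {
  f <- radplsc:::bipolar_sigmoid
  expect_equal(f(0), 0)
  expect_equal(f(100), 1, tolerance = 1e-10)
  expect_equal(f(-100), -1, tolerance = 1e-10)
  expect_true(all(abs(f(rnorm(100, sd = 10))) < 1))
})

test_that("backprop gradients equal central finite differences", {
  for (H in c(2L, 5L)) {
    m <- mlp_new(4, H, seed = 7)
    withr::with_seed(8, {
      x <- matrix(rnorm(6 * 4), 6, 4)
      y <- sample(c(-1, 1), 6, replace = TRUE)
    })
    g <- radplsc:::mlp_gradient(m, x, y)
    eps <- 1e-6
    num_grad <- function(mat_name, i, j) {
      mp <- m; mm <- m
      mp[[mat_name]][i, j] <- mp[[mat_name]][i, j] + eps
      mm[[mat_name]][i, j] <- mm[[mat_name]][i, j] - eps
      (radplsc:::mlp_gradient(mp, x, y)$mse -
         radplsc:::mlp_gradient(mm, x, y)$mse) / (2 * eps)
    }
    for (idx in list(c(1, 1), c(H, 2), c(1, 5))) {
      expect_equal(g$W1[idx[1], idx[2]], num_grad("W1", idx[1], idx[2]),
                   tolerance = 1e-5)
    }
    for (j in c(1, H + 1)) {
      expect_equal(g$W2[1, j], num_grad("W2", 1, j), tolerance = 1e-5)
    }
  }
})

test_that("zero learning rate and momentum leave weights unchanged", {
  m <- mlp_new(3, 2, seed = 1)
  withr::with_seed(2, x <- matrix(rnorm(12), 4, 3))
  tr <- mlp_train(m, x, c(1, -1, 1, -1),
                  mlp_train_config(learning_rate = 0, momentum = 0,
                                   max_epochs = 5))
  expect_identical(tr$W1, m$W1)
  expect_identical(tr$W2, m$W2)
  expect_length(tr$mse_trace, 5)
})

test_that("training is deterministic and separates a linear toy problem", {
  lat <- toy_latents(10, sep = 4, seed = 5)
  lm0 <- radplsc:::latent_matrix(lat)
  cfg <- mlp_train_config(max_epochs = 500)
  t1 <- mlp_train(mlp_new(8, 5, seed = 0), lm0$x, lm0$y, cfg)
  t2 <- mlp_train(mlp_new(8, 5, seed = 0), lm0$x, lm0$y, cfg)
  expect_identical(t1$W1, t2$W1)
  preds <- mlp_forward(t1, lm0$x)
  expect_equal(mean((preds >= 0) == (lm0$y > 0)), 1)
  # loss decreases overall
  expect_lt(tail(t1$mse_trace, 1), t1$mse_trace[1])
})

test_that("ROC analytics match hand-checkable cases and pROC", {
  r <- roc_analysis(c(0.9, 0.8, 0.3, 0.1), c("DIL", "DIL", "NT", "NT"))
  expect_equal(r$auroc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$distance, 0)
  expect_equal(r$ppv, 1)
  expect_equal(r$npv, 1)
  # scores equal to the labels
  y <- rep(c(1, -1), 5)
  expect_equal(roc_analysis(y, y)$auroc, 1)
  # label-independent scores give AUROC near 1/2
  withr::with_seed(11, {
    sc <- rnorm(2000)
    lab <- sample(c(1, -1), 2000, replace = TRUE)
  })
  expect_equal(roc_analysis(sc, lab)$auroc, 0.5, tolerance = 0.05)
  # monotone transforms leave the AUROC unchanged
  withr::with_seed(12, {
    sc2 <- rnorm(100)
    lab2 <- sample(c(1, -1), 100, replace = TRUE)
  })
  expect_equal(roc_analysis(sc2, lab2)$auroc,
               roc_analysis(tanh(3 * sc2) + 5, lab2)$auroc,
               tolerance = 1e-12)
  # independent oracle
  skip_if_not_installed("pROC")
  pr <- pROC::roc(lab2, sc2, quiet = TRUE, direction = "<")
  expect_equal(roc_analysis(sc2, lab2)$auroc, as.numeric(pROC::auc(pr)),
               tolerance = 1e-10)
  expect_error(roc_analysis(sc2, rep(1, 100)), "both classes")
})

test_that("LOOCV has one fold per subject and is reproducible", {
  lat <- toy_latents(8, sep = 3, seed = 6)
  cfg <- mlp_train_config(max_epochs = 40)
  cv1 <- mlp_loocv(lat, n_hidden = 3, config = cfg, seed = 2)
  cv2 <- mlp_loocv(lat, n_hidden = 3, config = cfg, seed = 2)
  expect_equal(cv1$n_folds, 8)
  expect_equal(cv1$train_fraction, 1 - 1 / 8)
  expect_equal(nrow(cv1$predictions), 16)  # every ROI predicted exactly once
  expect_identical(cv1$predictions, cv2$predictions)
  expect_length(cv1$ccf_curve, 40)
  expect_equal(cv1$auccf, mean(cv1$ccf_curve))
  expect_gte(cv1$roc$auroc, 0.9)           # well-separated toy
  expect_error(mlp_loocv(lat[lat$subject_id %in% c("s01", "s02"), ]),
               "at least 3")
})

test_that("architecture search returns a well-defined argmax", {
  lat <- toy_latents(6, sep = 3, seed = 7)
  cfg <- mlp_train_config(max_epochs = 20)
  res <- architecture_search(lat, hidden_range = c(2, 4), config = cfg)
  expect_true(res$chosen %in% c(2, 4))
  expect_equal(nrow(res$results), 2)
  # single-element range returns that size
  res1 <- architecture_search(lat, hidden_range = 5, config = cfg)
  expect_equal(res1$chosen, 5)
})

test_that("the stopping epoch follows the plateau definition", {
  curve <- c(0.5, 0.7, 0.85, 0.93, 0.97, 0.99, 1, 1, 1, 1)
  plateau <- mean(tail(curve, 1))
  expect_equal(stopping_epoch(curve), which(curve >= 0.9 * plateau)[1])
  expect_equal(stopping_epoch(rep(0.8, 10)), 1)
  # brute-force scan oracle on a noisy saturating curve
  withr::with_seed(13, noisy <- 1 - exp(-(1:50) / 7) + rnorm(50, sd = 0.01))
  n_tail <- ceiling(0.1 * 50)
  plateau <- mean(tail(noisy, n_tail))
  oracle <- min(which(noisy >= plateau * 0.9))
  expect_equal(stopping_epoch(noisy), oracle)
  # rise-based interpretation is selectable
  expect_equal(stopping_epoch(curve, mode = "of_rise"),
               which(curve >= 1 - 0.1 * (1 - 0.5))[1])
})

test_that("repeated splits produce the requested samples and valid CIs", {
  lat <- toy_latents(9, sep = 5, seed = 8)
  cfg <- mlp_train_config(max_epochs = 30)
  sp <- mlp_split_strategy(lat, n_iter = 20, n_hidden = 3, config = cfg,
                           seed = 3)
  expect_equal(nrow(sp$samples), 20)
  au <- sp$samples$auroc
  row <- sp$summary[sp$summary$metric == "auroc", ]
  expect_equal(row$mean, mean(au))
  # percentile CI matches a sort-based oracle
  s <- sort(au)
  expect_equal(row$ci_lo, quantile(s, 0.025, names = FALSE))
  expect_equal(row$ci_hi, quantile(s, 0.975, names = FALSE))
  expect_gte(row$mean, 0.9)   # strongly separated toy
})

test_that("cross-cohort evaluation is consistent and guards overlap", {
  lat_a <- toy_latents(8, sep = 5, seed = 9)
  lat_b <- toy_latents(10, sep = 5, seed = 10)
  lat_b$subject_id <- sub("^s", "t", lat_b$subject_id)
  cfg <- mlp_train_config(learning_rate = 0.1, max_epochs = 300)
  res <- mlp_cross_cohort(lat_a, lat_b, n_hidden = 3, config = cfg, seed = 1)
  expect_gte(res$sensitivity, 0.8)
  expect_gte(res$specificity, 0.8)
  # B = A reproduces the resubstitution ROC
  lat_a2 <- lat_a
  lat_a2$subject_id <- sub("^s", "u", lat_a2$subject_id)
  same <- mlp_cross_cohort(lat_a, lat_a2, n_hidden = 3, config = cfg, seed = 1)
  expect_equal(same$test_roc$auroc, same$train_roc$auroc, tolerance = 1e-12)
  expect_equal(same$sensitivity, same$train_roc$sensitivity)
  expect_error(mlp_cross_cohort(lat_a, lat_a), "overlap")
})
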