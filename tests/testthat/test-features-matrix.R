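test_that("run-length features of hand-enumerable images are exact", {
  # checkerboard: every horizontal and vertical run has length 1
  cb <- matrix(as.integer(make_fixture_image("checkerboard", 4)), 4, 4)
  mask <- matrix(TRUE, 4, 4)
  for (dir in list(c(0L, 1L), c(1L, 0L))) {
    runs <- radplsc:::glrl_runs(cb, mask, dir)
    expect_true(all(runs$length == 1))
    f <- radplsc:::glrl_features_from_runs(runs, sum(mask))
    expect_equal(unname(f["glrl_sre"]), 1)
    expect_equal(unname(f["glrl_lre"]), 1)
    expect_equal(unname(f["glrl_rp"]), 1)
  }

  # single row of one gray level: one horizontal run of length 4
  row4 <- matrix(2L, 1, 4)
  runs1 <- radplsc:::glrl_runs(row4, matrix(TRUE, 1, 4), c(0L, 1L))
  expect_equal(nrow(runs1), 1)
  f1 <- radplsc:::glrl_features_from_runs(runs1, 4)
  expect_equal(unname(f1["glrl_sre"]), 1 / 16)
  expect_equal(unname(f1["glrl_lre"]), 16)
})

test_that("run counts conserve the in-mask pixel total in every direction", {
  withr::with_seed(8, {
    img <- matrix(sample(0:3, 100, replace = TRUE), 10, 10)
    mask <- matrix(runif(100) < 0.7, 10, 10)
  })
  for (dir in radplsc:::glrl_directions) {
    runs <- radplsc:::glrl_runs(img, mask, dir)
    expect_equal(sum(runs$length), sum(mask))
  }
})

test_that("the run-length extractor returns 7 finite features", {
  f <- extract_glrl(make_fixture_image("checkerboard", 8))
  expect_length(f, 7)
  expect_true(all(is.finite(f)))
  expect_named(f, radplsc:::glrl_feature_names())
})

test_that("co-occurrence features of a 2-level checkerboard are exact", {
  # horizontal neighbours always differ by one level: P has only the
  # (1,2) and (2,1) cells, each 0.5
  cb <- matrix(rep(c(0L, 1L), 8), 4, 4)
  counts <- radplsc:::glcm_counts(cb, matrix(TRUE, 4, 4), c(1L, 0L), 2L)
  expect_true(all(counts == t(counts)))
  P <- counts / sum(counts)
  expect_equal(P, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  f <- radplsc:::glcm_features_from_matrix(P)
  expect_equal(unname(f["glcm_contrast"]), 1)
  expect_equal(unname(f["glcm_energy"]), 0.5)
  expect_equal(unname(f["glcm_entropy"]), 1)
  expect_equal(unname(f["glcm_dissimilarity"]), 1)
  expect_equal(unname(f["glcm_max_probability"]), 0.5)
  expect_equal(unname(f["glcm_homogeneity1"]), 0.5)
  expect_equal(unname(f["glcm_correlation1"]), -1)
})

test_that("a constant image yields the degenerate co-occurrence profile", {
  f <- extract_glcm(make_fixture_image("constant", 6))
  expect_equal(unname(f["glcm_contrast"]), 0)
  expect_equal(unname(f["glcm_energy"]), 1)
  expect_equal(unname(f["glcm_entropy"]), 0)
  expect_equal(unname(f["glcm_correlation1"]), 0)   # zero-variance convention
  expect_equal(unname(f["glcm_correlation2"]), 0)
})

test_that("co-occurrence marginal statistics match a brute-force oracle", {
  withr::with_seed(13, img <- matrix(sample(0:3, 36, replace = TRUE), 6, 6))
  f <- extract_glcm(img, bit_depth = 3)
  # oracle: enumerate symmetric co-occurring pairs over the 4 directions by
  # explicit loops on the same quantized levels
  q <- matrix(as.integer(quantize(img, bit_depth = 3)), 6, 6)
  n_lev <- 8L
  P <- matrix(0, n_lev, n_lev)
  for (dir in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    for (r in 1:6) for (cc in 1:6) {
      r2 <- r + dir[1]; c2 <- cc + dir[2]
      if (r2 >= 1 && r2 <= 6 && c2 >= 1 && c2 <= 6) {
        a <- q[r, cc] + 1L; b <- q[r2, c2] + 1L
        P[a, b] <- P[a, b] + 1
        P[b, a] <- P[b, a] + 1
      }
    }
  }
  P <- P / sum(P)
  expect_equal(unname(f["glcm_contrast"]),
               sum(outer(1:n_lev, 1:n_lev, function(i, j) (i - j)^2) * P))
  expect_equal(unname(f["glcm_energy"]), sum(P^2))
  p_nz <- P[P > 0]
  expect_equal(unname(f["glcm_entropy"]), -sum(p_nz * log2(p_nz)))
  mu <- sum(outer(1:n_lev, 1:n_lev, function(i, j) i) * P)
  expect_equal(unname(f["glcm_variance"]),
               sum(outer(1:n_lev, 1:n_lev, function(i, j) (i - mu)^2) * P))
})

test_that("masked pairs never cross the mask boundary", {
  img <- matrix(0L, 4, 4)
  img[, 3:4] <- 1L
  mask <- matrix(FALSE, 4, 4)
  mask[, 1:2] <- TRUE   # only the zero half is in-mask
  counts <- radplsc:::glcm_counts(img, mask, c(0L, 1L), 2L)
  expect_equal(sum(counts[2, ]), 0)   # level 1 never co-occurs
  expect_gt(counts[1, 1], 0)
})
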