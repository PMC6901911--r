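test_that("Dice obeys its identities", {
  a <- array(FALSE, c(2, 10, 10)); a[1, 3:6, 3:6] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- array(FALSE, c(2, 10, 10)); b[2, 1, 1] <- TRUE
  expect_equal(dice(a, b), 0)
  # 10x10 square against the same square shifted by 5 columns
  sq <- array(FALSE, c(1, 20, 20)); sq[1, 5:14, 1:10] <- TRUE
  sh <- array(FALSE, c(1, 20, 20)); sh[1, 5:14, 6:15] <- TRUE
  expect_equal(dice(sq, sh), 0.5)
  expect_equal(dice(sq, sh), dice(sh, sq))                 # symmetric
  expect_equal(dice(a & FALSE, b & FALSE), 1)              # both empty
  expect_error(dice(a, array(FALSE, c(1, 10, 10))), "shapes")
})

test_that("contour perturbation scales, shifts and guards emptiness", {
  # identity spec leaves the mask untouched
  m <- array(FALSE, c(5, 20, 20)); m[2:4, 8:12, 8:12] <- TRUE
  id <- perturb_contour(m, contour_perturb_spec(scale = 1, shift = c(0, 0, 0)))
  expect_identical(id, m)
  # a sphere scaled by 1.2 gains about 1.2^3 in volume
  sph <- array(FALSE, c(41, 41, 41))
  w <- as.matrix(expand.grid(1:41, 1:41, 1:41))
  sph[w[rowSums((w - 21)^2) <= 15^2, ]] <- TRUE
  big <- perturb_contour(sph, contour_perturb_spec(scale = 1.2,
                                                   shift = c(0, 0, 0)))
  ratio <- sum(big) / sum(sph)
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 1.85)
  expect_true(all(sph[big == FALSE] == FALSE))   # scaled-up mask contains core
  # +1 shift moves the centroid by one voxel per axis
  shifted <- perturb_contour(m, contour_perturb_spec(scale = 1,
                                                     shift = c(1, 1, 1)))
  c0 <- colMeans(which(m, arr.ind = TRUE))
  c1 <- colMeans(which(shifted, arr.ind = TRUE))
  expect_equal(unname(c1 - c0), c(1, 1, 1), tolerance = 1e-10)
  # perturbation that pushes the mask outside the volume errors
  edge <- array(FALSE, c(3, 6, 6)); edge[3, 5:6, 5:6] <- TRUE
  expect_error(perturb_contour(edge, contour_perturb_spec(shift = c(5, 5, 5))),
               "empty")
  expect_error(perturb_contour(edge & FALSE), "empty")
})

test_that("the variability critical value matches the F distribution", {
  expect_equal(round(variability_critical_f(19), 2), 4.11)
  expect_equal(variability_critical_f(10), qf(0.95, 1, 18))
})

test_that("probability maps are constant on constant inputs and bounded", {
  pl <- small_pipeline()
  s <- pl$cohort[[1]]
  const <- s
  const$t2w_volume <- array(50, dim(s$t2w_volume))
  const$adc_volume <- array(1e-3, dim(s$adc_volume))
  pm <- probability_map(const, pl$model, pl$selection, pl$ann,
                        window = 25, stride = 13, slices = 6)
  vals <- as.numeric(pm$prob[["6"]])
  expect_equal(max(vals) - min(vals), 0, tolerance = 1e-12)
  expect_true(all(vals >= 0 & vals <= 1))
  expect_error(probability_map(const, pl$model, pl$selection, pl$ann,
                               window = 100), "window larger")
})

test_that("non-overlapping tiling yields floor(dim/window) positions", {
  pl <- small_pipeline()
  s <- pl$cohort[[1]]
  pm <- probability_map(s, pl$model, pl$selection, pl$ann,
                        window = 25, stride = 25, slices = 6)
  expect_equal(length(pm$starts_y), floor(64 / 25))
  expect_equal(length(pm$starts_x), floor(64 / 25))
})

test_that("the map localises an implanted lesion", {
  pl <- small_pipeline()
  s <- pl$cohort[[2]]
  mid <- 6
  pm <- probability_map(s, pl$model, pl$selection, pl$ann,
                        window = 25, stride = 6, slices = mid)
  m <- pm$prob[[as.character(mid)]]
  expect_true(all(m >= 0 & m <= 1))
  # windows centred inside the DIL score higher than windows far from it
  dil_c <- colMeans(which(s$dil_mask[mid, , ], arr.ind = TRUE))
  inside <- outer(pm$centers_y, pm$centers_x,
                  function(y, x) sqrt((y - dil_c[1])^2 + (x - dil_c[2])^2)) < 8
  outside <- outer(pm$centers_y, pm$centers_x,
                   function(y, x) sqrt((y - dil_c[1])^2 + (x - dil_c[2])^2)) > 20
  expect_gt(mean(m[inside]), mean(m[outside]))
  # thresholding identities
  all_cov <- threshold_map(pm, p_thr = 0)
  none <- threshold_map(pm, p_thr = 1)
  expect_equal(sum(none), 0)
  side_y <- max(pm$starts_y) + 25 - min(pm$starts_y)
  side_x <- max(pm$starts_x) + 25 - min(pm$starts_x)
  expect_equal(sum(all_cov[mid, , ]), side_y * side_x)
  expect_equal(sum(all_cov[-mid, , ]), 0)
  # deterministic given frozen models
  pm2 <- probability_map(s, pl$model, pl$selection, pl$ann,
                         window = 25, stride = 6, slices = mid)
  expect_identical(pm$prob, pm2$prob)
})

test_that("identity perturbation gives F near zero for every latent", {
  pl <- small_pipeline()
  subjects <- pl$cohort[1:4]
  vt <- contour_variability_test(
    subjects, pl$model, pl$selection,
    spec = contour_perturb_spec(scale = 1, shift = c(0, 0, 0)))
  expect_true(all(vt$results$f_statistic < 1e-20))
  expect_true(vt$all_pass)
  expect_equal(vt$results$f_critical[1], variability_critical_f(4))
  expect_equal(nrow(vt$results), nrow(pl$selection$selected))
})

test_that("contour sensitivity grows with perturbation severity", {
  # the ANOVA mechanism: zero for identity contours, monotone in severity
  pl <- small_pipeline()
  subjects <- pl$cohort[1:6]
  mild <- contour_variability_test(
    subjects, pl$model, pl$selection,
    spec = contour_perturb_spec(scale = 1.05, shift = c(0, 1, 1)))
  full <- contour_variability_test(subjects, pl$model, pl$selection)
  expect_true(all(mild$results$f_statistic >= 0))
  expect_equal(mild$results$latent, full$results$latent)
  # the homogeneous synthetic cohort makes the default 1.2x + 1-voxel
  # perturbation clearly detectable, and milder contours shift scores less
  expect_true(all(full$results$f_statistic > mild$results$f_statistic))
})
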