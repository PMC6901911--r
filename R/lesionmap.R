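# Sliding-window DIL probability mapping, Dice evaluation and the
# contour-variability robustness test.

# Latent feature row(s) for window feature matrices, in the column order of
# the selection's feature table.
project_windows <- function(model, selection, feats_t2w, feats_adc) {
  Lx <- plsc_project(model, feats_t2w, "X")
  Ly <- plsc_project(model, feats_adc, "Y")
  sel <- selection$selected
  out <- matrix(0, nrow(Lx), nrow(sel))
  for (i in seq_len(nrow(sel))) {
    out[, i] <- if (sel$block[i] == "T2W") Lx[, sel$dimension[i]]
                else Ly[, sel$dimension[i]]
  }
  colnames(out) <- sprintf("%s_lv%d", tolower(sel$block), sel$dimension)
  out
}

#' Sliding-window DIL probability map
#'
#' For every window position on the chosen slices, the full 168-feature
#' vector is extracted from each harmonized modality (the whole window is
#' the ROI), projected through the frozen PLSC model onto the selected
#' latent variables, scored by the frozen MLP, and mapped to a probability
#' `(score + 1) / 2`. Both volumes are harmonized by the subject's NT-mask
#' mean before sampling.
#'
#' @param subject a `synth_subject` (or any list with `t2w_volume`,
#'   `adc_volume`, `nt_mask`).
#' @param model a `plsc_fit` fitted on the training cohort.
#' @param selection the `latent_selection` used to train the MLP.
#' @param ann a trained `mlp_model`.
#' @param window square window side in voxels (default 25).
#' @param stride window step in voxels (default 1 = dense map).
#' @param slices z indices to map (default: all slices).
#' @param harmonize_adc harmonize the ADC volume too (must match training).
#' @return object of class `probability_map`: list with `prob` (list of
#'   per-slice matrices over window positions), `centers_y`, `centers_x`,
#'   `slices`, `window`, `stride`, `dim`.
#' @export
probability_map <- function(subject, model, selection, ann, window = 25L,
                            stride = 1L, slices = NULL,
                            harmonize_adc = TRUE) {
  shp <- dim(subject$t2w_volume)
  window <- as.integer(window); stride <- as.integer(stride)
  if (window > shp[2] || window > shp[3])
    stop("window larger than the slice")
  slices <- slices %||% seq_len(shp[1])
  t2w <- harmonize(subject$t2w_volume, nt_mask = subject$nt_mask)
  adc <- if (harmonize_adc) harmonize(subject$adc_volume,
                                      nt_mask = subject$nt_mask)
         else subject$adc_volume
  ys <- seq(1L, shp[2] - window + 1L, by = stride)
  xs <- seq(1L, shp[3] - window + 1L, by = stride)
  prob <- list()
  for (z in slices) {
    ft_t2w <- matrix(NA_real_, length(ys) * length(xs), 168L)
    ft_adc <- ft_t2w
    r <- 0L
    for (y0 in ys) for (x0 in xs) {
      r <- r + 1L
      wy <- y0:(y0 + window - 1L); wx <- x0:(x0 + window - 1L)
      ft_t2w[r, ] <- extract_all(t2w[z, wy, wx])
      ft_adc[r, ] <- extract_all(adc[z, wy, wx])
    }
    lat <- project_windows(model, selection, ft_t2w, ft_adc)
    p <- score_to_probability(mlp_forward(ann, lat))
    prob[[as.character(z)]] <- matrix(p, length(ys), length(xs), byrow = TRUE)
  }
  structure(list(prob = prob,
                 centers_y = ys + (window - 1L) / 2,
                 centers_x = xs + (window - 1L) / 2,
                 starts_y = ys, starts_x = xs,
                 slices = slices, window = window, stride = stride,
                 dim = shp),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %d slice(s), %dx%d windows (size %d, stride %d)\n",
              length(x$prob), length(x$starts_y), length(x$starts_x),
              x$window, x$stride))
  invisible(x)
}

#' Heatmap of one slice of a probability map
#' @param object a `probability_map`.
#' @param slice z index to display (default: first mapped slice).
#' @param ... unused.
#' @method autoplot probability_map
#' @export
autoplot.probability_map <- function(object, slice = object$slices[1], ...) {
  m <- object$prob[[as.character(slice)]]
  df <- tidyr::expand_grid(yi = seq_along(object$centers_y),
                           xi = seq_along(object$centers_x))
  df$p <- m[cbind(df$yi, df$xi)]
  df$y <- object$centers_y[df$yi]
  df$x <- object$centers_x[df$xi]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "P(DIL)") +
    ggplot2::theme_minimal()
}

#' Resample a probability map onto the voxel grid
#'
#' Each covered voxel receives the probability of its nearest window
#' centre; voxels outside the covered region (and unmapped slices) are 0.
#'
#' @param map a `probability_map`.
#' @return numeric volume of the input geometry with values in \[0, 1\].
#' @export
probability_volume <- function(map) {
  out <- array(0, map$dim)
  cov_y <- seq(min(map$starts_y), max(map$starts_y) + map$window - 1L)
  cov_x <- seq(min(map$starts_x), max(map$starts_x) + map$window - 1L)
  near <- function(v, centers) {
    vapply(v, function(p) which.min(abs(centers - p)), 0L)
  }
  iy <- near(cov_y, map$centers_y)
  ix <- near(cov_x, map$centers_x)
  for (z in map$slices) {
    m <- map$prob[[as.character(z)]]
    out[z, cov_y, cov_x] <- m[iy, ix, drop = FALSE]
  }
  out
}

#' Threshold a probability map into a voxel-grid patch mask
#'
#' Each covered voxel (inside the union of the sampling windows) receives
#' the probability of its nearest window centre; voxels with probability
#' strictly above `p_thr` form the DIL patch.
#'
#' @param map a `probability_map`.
#' @param p_thr probability threshold (reference analysis uses 0.001).
#' @return logical volume of the input geometry.
#' @export
threshold_map <- function(map, p_thr = 0.001) {
  probability_volume(map) > p_thr
}

#' Dice overlap coefficient of two binary masks
#'
#' `2 |A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param mask_a,mask_b same-shape binary masks.
#' @return numeric in \[0, 1\].
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) stop("mask shapes differ")
  a <- mask_a > 0; b <- mask_b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Contour perturbation specification
#' @param scale isotropic scale factor about the mask centroid (default 1.2).
#' @param shift voxel translation applied after scaling, one value per axis
#'   (z, y, x); default +1 voxel along every axis.
#' @return list of class `contour_perturb_spec`.
#' @export
contour_perturb_spec <- function(scale = 1.2, shift = c(1, 1, 1)) {
  stopifnot(scale > 0, length(shift) == 3)
  structure(list(scale = scale, shift = as.numeric(shift)),
            class = "contour_perturb_spec")
}

#' Perturb a contour mask (scale about centroid, then shift)
#'
#' The mask is scaled isotropically about its centroid with nearest-
#' neighbour resampling (inverse mapping), then translated by the shift
#' vector; the result is clipped to the volume.
#'
#' @param mask non-empty binary volume.
#' @param spec a [contour_perturb_spec()].
#' @return perturbed logical volume.
#' @export
perturb_contour <- function(mask, spec = contour_perturb_spec()) {
  m <- mask > 0
  if (!any(m)) stop("mask is empty")
  shp <- dim(m)
  w <- which(m, arr.ind = TRUE)
  ctr <- colMeans(w)
  # inverse mapping: target voxel looks up its source at centre + d/scale
  idx <- as.matrix(expand.grid(z = seq_len(shp[1]), y = seq_len(shp[2]),
                               x = seq_len(shp[3])))
  src <- sweep(sweep(idx, 2, ctr, `-`) / spec$scale, 2, ctr, `+`)
  src <- round(src)
  inside <- src[, 1] >= 1 & src[, 1] <= shp[1] &
            src[, 2] >= 1 & src[, 2] <= shp[2] &
            src[, 3] >= 1 & src[, 3] <= shp[3]
  scaled <- array(FALSE, shp)
  scaled[idx[inside, , drop = FALSE]] <- m[src[inside, , drop = FALSE]]
  # translate
  out <- array(FALSE, shp)
  w2 <- which(scaled, arr.ind = TRUE)
  w2 <- sweep(w2, 2, spec$shift, `+`)
  keep <- w2[, 1] >= 1 & w2[, 1] <= shp[1] &
          w2[, 2] >= 1 & w2[, 2] <= shp[2] &
          w2[, 3] >= 1 & w2[, 3] <= shp[3]
  if (!any(keep)) stop("perturbed mask empty after clipping")
  out[w2[keep, , drop = FALSE]] <- TRUE
  out
}

#' Critical F value for the contour-variability ANOVA
#'
#' Two groups of `n` observations: `qf(1 - alpha, 1, 2n - 2)`. For n = 19
#' at alpha = 0.05 this is 4.11.
#'
#' @param n subjects per group.
#' @param alpha significance level.
#' @return critical F value.
#' @export
variability_critical_f <- function(n, alpha = 0.05) {
  qf(1 - alpha, 1, 2 * n - 2)
}

#' Contour-variability robustness test
#'
#' Radiomics extraction and PLSC projection are repeated with perturbed DIL
#' and NT contours for a subject subset; for each selected latent variable a
#' one-way ANOVA compares the original and perturbed per-subject scores
#' (DIL rows; two groups of n). The latent variables are robust when every
#' F statistic stays below the critical value `qf(0.95, 1, 2n - 2)`.
#'
#' @param subjects list of `synth_subject` (e.g. a cohort subset).
#' @param model a fitted `plsc_fit`.
#' @param selection the `latent_selection` in use.
#' @param spec a [contour_perturb_spec()].
#' @param alpha significance level for the critical value.
#' @param roi which ROI rows enter the test (default DIL).
#' @param harmonize_adc must match the training extraction settings.
#' @return object of class `variability_test`: tibble `results` with per
#'   latent variable `f_statistic`, `f_critical`, `pass`, plus `all_pass`.
#' @export
contour_variability_test <- function(subjects, model, selection,
                                     spec = contour_perturb_spec(),
                                     alpha = 0.05, roi = "DIL",
                                     harmonize_adc = TRUE) {
  if (length(subjects) < 3) stop("need at least 3 subjects")
  ids <- vapply(subjects, `[[`, "", "subject_id")
  feats_orig <- extract_features(subjects, harmonize_adc = harmonize_adc)
  dil_pert <- lapply(subjects, function(s) perturb_contour(s$dil_mask, spec))
  nt_pert <- lapply(subjects, function(s) perturb_contour(s$nt_mask, spec))
  names(dil_pert) <- ids; names(nt_pert) <- ids
  feats_pert <- extract_features(subjects, harmonize_adc = harmonize_adc,
                                 dil_masks = dil_pert, nt_masks = nt_pert)
  lat_orig <- project_selection(model, selection, feats_orig)
  lat_pert <- project_selection(model, selection, feats_pert)
  score_cols <- setdiff(names(lat_orig), c("subject_id", "roi", "group_tag"))
  o <- dplyr::filter(lat_orig, .data$roi == !!roi)
  p <- dplyr::filter(lat_pert, .data$roi == !!roi)
  n <- nrow(o)
  fc <- variability_critical_f(n, alpha)
  res <- dplyr::bind_rows(lapply(score_cols, function(cn) {
    vals <- c(o[[cn]], p[[cn]])
    grp <- factor(rep(c("orig", "pert"), each = n))
    f <- unname(oneway.test(vals ~ grp, var.equal = TRUE)$statistic)
    tibble::tibble(latent = cn, f_statistic = f, f_critical = fc,
                   pass = f < fc)
  }))
  structure(list(results = res, all_pass = all(res$pass), n = n,
                 spec = spec, alpha = alpha),
            class = "variability_test")
}

#' @export
print.variability_test <- function(x, ...) {
  cat(sprintf("<variability_test> n = %d per group, Fc = %.2f, %s\n",
              x$n, x$results$f_critical[1],
              if (x$all_pass) "all latent variables robust"
              else "some latent variables sensitive"))
  print(x$results)
  invisible(x)
}
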