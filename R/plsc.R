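# Two-block partial least squares correlation (PLSC).
#
# Given two observation blocks X (T2W features) and Y (ADC features) with
# aligned rows (one row per ROI), PLSC finds pairs of latent vectors with
# maximal covariance: the SVD of the cross-block covariance
# R = X' Y / (n - 1) yields saliences U, V (column-orthonormal feature
# loadings) and singular values d; latent scores are Lx = X U, Ly = Y V.
# The inertia sum(d^2) = ||R||_F^2 measures the total cross-block
# covariance captured.

#' Build aligned, standardized observation blocks from a feature table
#'
#' One block per modality; rows are ROIs (subject x DIL/NT) in identical
#' order across blocks; columns are z-scored (mean 0, unit SD). Zero-variance
#' columns are set to all zeros with a warning.
#'
#' @param feature_table tibble from [extract_features()].
#' @return list with matrices `X` (T2W) and `Y` (ADC), a `labels` tibble
#'   (`subject_id`, `roi`, `group_tag`) aligned to the rows, and the
#'   per-block standardization parameters (`center`, `scale`).
#' @export
build_blocks <- function(feature_table) {
  fn <- feature_names()
  stopifnot(all(fn %in% names(feature_table)))
  key <- function(tb) paste(tb$subject_id, tb$roi)
  xs <- dplyr::arrange(dplyr::filter(feature_table, .data$modality == "T2W"),
                       .data$subject_id, .data$roi)
  ys <- dplyr::arrange(dplyr::filter(feature_table, .data$modality == "ADC"),
                       .data$subject_id, .data$roi)
  if (nrow(xs) == 0 || nrow(ys) == 0 || !identical(key(xs), key(ys)))
    stop("every ROI must have feature vectors for both modalities")
  std <- function(m) {
    ctr <- colMeans(m)
    scl <- apply(m, 2, sd)
    zero <- !is.finite(scl) | scl == 0
    if (any(zero)) {
      warning(sum(zero), " zero-variance column(s) set to 0")
      scl[zero] <- 1
    }
    z <- scale(m, center = ctr, scale = scl)
    z[, zero] <- 0
    list(z = unname(as.matrix(z)), center = ctr, scale = scl)
  }
  sx <- std(as.matrix(xs[, fn]))
  sy <- std(as.matrix(ys[, fn]))
  list(X = sx$z, Y = sy$z,
       labels = tibble::tibble(subject_id = xs$subject_id, roi = xs$roi,
                               group_tag = xs$group_tag),
       center = list(X = sx$center, Y = sy$center),
       scale = list(X = sx$scale, Y = sy$scale),
       feature_names = fn)
}

# Deterministic sign convention: make the largest-magnitude loading of each
# U column positive, flipping the paired V column with it.
apply_sign_convention <- function(U, V) {
  for (k in seq_len(ncol(U))) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  list(U = U, V = V)
}

#' Fit a two-block PLSC model
#'
#' SVD of the cross-block covariance of the standardized blocks. A
#' deterministic sign convention (largest-magnitude T2W loading positive) is
#' applied to each salience pair.
#'
#' @param blocks output of [build_blocks()], or a list with aligned numeric
#'   matrices `X` and `Y` (already standardized).
#' @param n_components number of latent dimensions to keep (default: full
#'   rank).
#' @return object of class `plsc_fit` with saliences `U`, `V`, singular
#'   values `d`, latent scores `Lx`, `Ly`, `inertia`, row `labels` and the
#'   standardization parameters.
#' @export
fit_plsc <- function(blocks, n_components = NULL) {
  X <- blocks$X; Y <- blocks$Y
  stopifnot(is.matrix(X), is.matrix(Y), nrow(X) == nrow(Y), nrow(X) >= 3)
  n <- nrow(X)
  R <- crossprod(X, Y) / (n - 1)
  if (max(abs(R)) == 0) stop("cross-block covariance has rank 0")
  L <- n_components %||% min(dim(R))
  sv <- svd(R, nu = L, nv = L)
  sgn <- apply_sign_convention(sv$u, sv$v)
  U <- sgn$U; V <- sgn$V
  structure(
    list(U = U, V = V, d = sv$d[seq_len(L)],
         Lx = X %*% U, Ly = Y %*% V,
         inertia = sum(sv$d^2),
         labels = blocks$labels,
         center = blocks$center, scale = blocks$scale,
         feature_names = blocks$feature_names %||%
           paste0("f", seq_len(nrow(R)))),
    class = "plsc_fit")
}

#' @export
print.plsc_fit <- function(x, ...) {
  cat(sprintf("<plsc_fit> %d ROIs, %d x %d features, %d latent dims, inertia %.4g\n",
              nrow(x$Lx), nrow(x$U), nrow(x$V), length(x$d), x$inertia))
  invisible(x)
}

#' Project new feature vectors into a fitted PLSC space
#'
#' New rows are standardized with the model's stored column means/scales and
#' multiplied by the saliences.
#'
#' @param model a `plsc_fit`.
#' @param new_features matrix (rows x 168) or tibble containing the
#'   canonical feature columns.
#' @param block `"X"` (T2W) or `"Y"` (ADC).
#' @return matrix of latent scores (rows x n_components).
#' @export
plsc_project <- function(model, new_features, block = c("X", "Y")) {
  block <- match.arg(block)
  if (is.data.frame(new_features))
    new_features <- as.matrix(new_features[, model$feature_names])
  if (is.null(dim(new_features)))
    new_features <- matrix(new_features, nrow = 1)
  W <- if (block == "X") model$U else model$V
  if (ncol(new_features) != nrow(W))
    stop("feature dimensionality mismatch: got ", ncol(new_features),
         ", expected ", nrow(W))
  z <- sweep(new_features, 2, model$center[[block]], `-`)
  z <- sweep(z, 2, model$scale[[block]], `/`)
  z %*% W
}

#' Tidy the saliences of a PLSC fit
#' @param x a `plsc_fit`.
#' @param ... unused.
#' @return tibble with feature, modality block, latent dimension, loading.
#' @method tidy plsc_fit
#' @export
tidy.plsc_fit <- function(x, ...) {
  L <- length(x$d)
  dplyr::bind_rows(
    tibble::tibble(feature = rep(x$feature_names, L),
                   block = "T2W",
                   dimension = rep(seq_len(L), each = nrow(x$U)),
                   loading = as.numeric(x$U)),
    tibble::tibble(feature = rep(x$feature_names, L),
                   block = "ADC",
                   dimension = rep(seq_len(L), each = nrow(x$V)),
                   loading = as.numeric(x$V)))
}

#' One-line summary of a PLSC fit
#' @param x a `plsc_fit`.
#' @param ... unused.
#' @method glance plsc_fit
#' @export
glance.plsc_fit <- function(x, ...) {
  tibble::tibble(n_rows = nrow(x$Lx), n_features = nrow(x$U),
                 n_components = length(x$d), inertia = x$inertia,
                 d1 = x$d[1])
}

#' Latent scores of a PLSC fit as a tibble
#' @param model a `plsc_fit`.
#' @param dimensions which latent dimensions to include.
#' @return tibble in long format with block, dimension and score columns.
#' @export
latent_scores <- function(model, dimensions = seq_along(model$d)) {
  dplyr::bind_rows(lapply(dimensions, function(k) {
    dplyr::bind_rows(
      dplyr::mutate(model$labels, block = "T2W", dimension = k,
                    score = model$Lx[, k]),
      dplyr::mutate(model$labels, block = "ADC", dimension = k,
                    score = model$Ly[, k]))
  }))
}

#' Scatter plot of paired latent scores
#' @param object a `plsc_fit`.
#' @param dimension latent dimension to display.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot plsc_fit
#' @export
autoplot.plsc_fit <- function(object, dimension = 1, ...) {
  df <- tibble::tibble(lx = object$Lx[, dimension],
                       ly = object$Ly[, dimension],
                       roi = object$labels$roi)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lx, y = .data$ly,
                                   colour = .data$roi)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = sprintf("T2W latent score %d", dimension),
                  y = sprintf("ADC latent score %d", dimension),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
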