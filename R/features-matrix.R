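# Gray-level run-length and co-occurrence families.

# The four in-plane directions as (dy, dx) unit offsets.
glrl_directions <- list(h = c(0L, 1L), v = c(1L, 0L),
                        d = c(1L, 1L), a = c(1L, -1L))

# Maximal scan lines covering a nr x nc grid along one direction; each line
# is a 2-column matrix of (row, col) indices ordered along the direction.
# Cached per (nr, nc, dir) since grids repeat across slices and subjects.
.scan_cache <- new.env(parent = emptyenv())

scan_lines <- function(nr, nc, dir) {
  key0 <- paste(nr, nc, dir[1], dir[2], sep = ":")
  hit <- .scan_cache[[key0]]
  if (!is.null(hit)) return(hit)
  idx <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  key <- switch(paste(dir, collapse = ","),
    "0,1" = idx$row,
    "1,0" = idx$col,
    "1,1" = idx$col - idx$row,
    "1,-1" = idx$col + idx$row,
    stop("unsupported direction"))
  ord <- order(key, idx$row, idx$col)
  out <- split.data.frame(idx[ord, ], key[ord])
  .scan_cache[[key0]] <- out
  out
}

# Run-length counts of a quantized slice along one direction, restricted to
# in-mask pixels (runs break at mask boundaries). Returns a data.frame with
# columns level, length, count.
glrl_runs <- function(levels_mat, mask, dir) {
  nr <- nrow(levels_mat); nc <- ncol(levels_mat)
  vals <- levels_mat
  vals[!mask] <- NA_integer_
  runs_level <- integer(0); runs_len <- integer(0)
  for (line in scan_lines(nr, nc, dir)) {
    seqv <- vals[cbind(line$row, line$col)]
    r <- rle(as.vector(seqv))
    keep <- !is.na(r$values)
    runs_level <- c(runs_level, r$values[keep])
    runs_len <- c(runs_len, r$lengths[keep])
  }
  data.frame(level = runs_level, length = runs_len)
}

# The seven Galloway descriptors from a run table (levels are 0-based and
# shifted to 1-based for the gray-level emphases).
glrl_features_from_runs <- function(runs, n_pixels) {
  nr_runs <- nrow(runs)
  if (nr_runs == 0) return(setNames(rep(0, 7), glrl_feature_names()))
  g <- runs$level + 1
  l <- runs$length
  gln <- sum(tapply(rep(1, nr_runs), g, sum)^2)
  rln <- sum(tapply(rep(1, nr_runs), l, sum)^2)
  c(glrl_sre = sum(1 / l^2) / nr_runs,
    glrl_lre = sum(l^2) / nr_runs,
    glrl_gln = gln / nr_runs,
    glrl_rp = nr_runs / n_pixels,
    glrl_rln = rln / nr_runs,
    glrl_lgre = sum(1 / g^2) / nr_runs,
    glrl_hgre = sum(g^2) / nr_runs)
}

glrl_feature_names <- function() {
  c("glrl_sre", "glrl_lre", "glrl_gln", "glrl_rp", "glrl_rln",
    "glrl_lgre", "glrl_hgre")
}

#' Gray-level run-length features (7)
#'
#' Intensities are quantized to `2^bit_depth` levels over the in-mask range;
#' runs are counted within the mask along the four in-plane directions
#' (runs break at mask boundaries). The seven Galloway descriptors (SRE,
#' LRE, GLN, RP, RLN, LGRE, HGRE) are computed per direction, averaged over
#' directions, then averaged over slices.
#'
#' @inheritParams extract_ibhf
#' @param bit_depth run-length quantization depth (default 4, i.e. 16 levels).
#' @return named numeric vector of length 7.
#' @export
extract_glrl <- function(roi_values, mask = NULL, bit_depth = 4L) {
  prep <- roi_slices(roi_values, mask, min_pixels = if (is.null(mask)) 1L else 16L)
  rng <- range(prep$values)
  rows <- lapply(prep$slices, function(sl) {
    q <- quantize(sl$img, bit_depth = bit_depth, range = rng)
    np <- sum(sl$mask)
    per_dir <- lapply(glrl_directions, function(dir) {
      glrl_features_from_runs(glrl_runs(q, sl$mask, dir), np)
    })
    average_slices(per_dir)
  })
  average_slices(rows)
}

# Symmetric co-occurrence counts of a quantized slice for one (dy, dx)
# offset, counting only pairs with both pixels in-mask.
glcm_counts <- function(levels_mat, mask, dir, n_levels) {
  nr <- nrow(levels_mat); nc <- ncol(levels_mat)
  dy <- dir[1]; dx <- dir[2]
  r1 <- max(1L, 1L - dy):min(nr, nr - dy)
  c1 <- max(1L, 1L - dx):min(nc, nc - dx)
  a <- levels_mat[r1, c1, drop = FALSE]
  b <- levels_mat[r1 + dy, c1 + dx, drop = FALSE]
  ok <- mask[r1, c1, drop = FALSE] & mask[r1 + dy, c1 + dx, drop = FALSE]
  ai <- as.integer(a[ok]); bi <- as.integer(b[ok])
  counts <- tabulate(ai * n_levels + bi + 1L, nbins = n_levels^2) +
    tabulate(bi * n_levels + ai + 1L, nbins = n_levels^2)
  matrix(counts, n_levels, n_levels)
}

glcm_feature_names <- function() {
  paste0("glcm_", c("autocorrelation", "contrast", "correlation2",
                    "correlation1", "cluster_prominence", "cluster_shade",
                    "dissimilarity", "energy", "entropy", "homogeneity1",
                    "homogeneity2", "max_probability", "variance",
                    "sum_average", "sum_variance", "sum_entropy",
                    "difference_variance", "difference_entropy",
                    "imc1", "imc2", "idn", "idmn"))
}

# The 22 Haralick-family statistics of a normalized symmetric GLCM.
glcm_features_from_matrix <- function(P) {
  n <- nrow(P)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(n) * px); muy <- sum(seq_len(n) * py)
  sx <- sqrt(sum((seq_len(n) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(n) - muy)^2 * py))

  # diagonal-sum and diagonal-difference marginals (single pass each)
  k_sum <- 2:(2 * n)
  ps <- rowsum(as.vector(P), as.vector(i + j))
  p_sum <- numeric(length(k_sum))
  p_sum[as.integer(rownames(ps)) - 1L] <- ps[, 1]
  k_diff <- 0:(n - 1)
  pd <- rowsum(as.vector(P), as.vector(abs(i - j)))
  p_diff <- numeric(length(k_diff))
  p_diff[as.integer(rownames(pd)) + 1L] <- pd[, 1]

  sum_avg <- sum(k_sum * p_sum)
  diff_avg <- sum(k_diff * p_diff)
  hx <- shannon_probs(px); hy <- shannon_probs(py)
  hxy <- shannon_probs(P)
  pxpy <- px[i] * py[j]
  nz <- P > 0
  hxy1 <- -sum(P[nz & pxpy > 0] * log2(pxpy[nz & pxpy > 0]))
  hxy2 <- shannon_probs(pxpy)

  corr <- if (sx > 0 && sy > 0) (sum(i * j * P) - mux * muy) / (sx * sy) else 0
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))

  setNames(c(
    sum(i * j * P),                                   # autocorrelation
    sum((i - j)^2 * P),                               # contrast
    corr,                                             # correlation (2)
    if (sx > 0 && sy > 0) sum((i - mux) * (j - muy) * P) / (sx * sy) else 0,
    sum((i + j - mux - muy)^4 * P),                   # cluster prominence
    sum((i + j - mux - muy)^3 * P),                   # cluster shade
    sum(abs(i - j) * P),                              # dissimilarity
    sum(P^2),                                         # energy
    hxy,                                              # entropy
    sum(P / (1 + abs(i - j))),                        # homogeneity (1)
    sum(P / (1 + (i - j)^2)),                         # homogeneity (2)
    max(P),                                           # maximum probability
    sum((i - mux)^2 * P),                             # sum of squares variance
    sum_avg,                                          # sum average
    sum((k_sum - sum_avg)^2 * p_sum),                 # sum variance
    shannon_probs(p_sum),                             # sum entropy
    sum((k_diff - diff_avg)^2 * p_diff),              # difference variance
    shannon_probs(p_diff),                            # difference entropy
    imc1, imc2,
    sum(P / (1 + abs(i - j) / n)),                    # idn
    sum(P / (1 + (i - j)^2 / n^2))                    # idmn
  ), glcm_feature_names())
}

#' Gray-level co-occurrence features (22)
#'
#' Intensities are quantized (8-bit by default) over the in-mask range; a
#' symmetric co-occurrence matrix is accumulated over the four in-plane unit
#' offsets and all slices (both pixels of a pair must be in-mask), normalised
#' once, and the 22 Haralick-family statistics are computed from it.
#' Correlation-type features are 0 by convention when a marginal SD is zero.
#'
#' @inheritParams extract_ibhf
#' @param bit_depth co-occurrence quantization depth (default 8).
#' @return named numeric vector of length 22.
#' @export
extract_glcm <- function(roi_values, mask = NULL, bit_depth = 8L) {
  prep <- roi_slices(roi_values, mask, min_pixels = if (is.null(mask)) 1L else 16L)
  rng <- range(prep$values)
  n_levels <- 2L^as.integer(bit_depth)
  total <- matrix(0, n_levels, n_levels)
  for (sl in prep$slices) {
    q <- quantize(sl$img, bit_depth = bit_depth, range = rng)
    for (dir in glrl_directions) {
      total <- total + glcm_counts(q, sl$mask, dir, n_levels)
    }
  }
  s <- sum(total)
  if (s == 0) stop("no co-occurring in-mask pixel pairs")
  glcm_features_from_matrix(total / s)
}
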