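# Transform-based texture families: Laws kernels, discrete orthonormal
# Stockwell transform, 2D wavelet decomposition, Gabor filter bank.

## ---- Laws texture energy ----------------------------------------------

laws_1d <- list(
  L5 = c(1, 4, 6, 4, 1),
  E5 = c(-1, -2, 0, 2, 1),
  S5 = c(-1, 0, 2, 0, -1),
  R5 = c(1, -4, 6, -4, 1)
)

# The 9 map groups; symmetric pairs are averaged pixelwise before the
# energy/entropy operators.
laws_map_groups <- list(
  l5e5 = c("L5E5", "E5L5"), l5r5 = c("L5R5", "R5L5"),
  e5s5 = c("E5S5", "S5E5"), s5s5 = "S5S5", r5r5 = "R5R5",
  l5s5 = c("L5S5", "S5L5"), e5e5 = "E5E5",
  e5r5 = c("E5R5", "R5E5"), s5r5 = c("S5R5", "R5S5")
)

laws_kernel <- function(name) {
  a <- laws_1d[[substr(name, 1, 2)]]
  b <- laws_1d[[substr(name, 3, 4)]]
  outer(a, b)   # first factor along rows (y), second along columns (x)
}

laws_feature_names <- function() {
  as.vector(t(outer(names(laws_map_groups), c("energy", "entropy"),
                    function(g, s) paste("laws", g, s, sep = "_"))))
}

#' Laws texture features (18)
#'
#' The four 5-tap kernels L5/E5/S5/R5 are combined into nine 5x5 map groups
#' (outer products; transposed pairs averaged pixelwise); the energy and
#' entropy of each map, pooled over in-mask pixels, are averaged over slices.
#'
#' @inheritParams extract_ibhf
#' @return named numeric vector of length 18.
#' @export
extract_laws <- function(roi_values, mask = NULL) {
  prep <- roi_slices(roi_values, mask, min_pixels = if (is.null(mask)) 1L else 16L)
  if (nrow(prep$slices[[1]]$img) < 5 || ncol(prep$slices[[1]]$img) < 5)
    stop("Laws features need an ROI bounding box of at least 5x5")
  rows <- lapply(prep$slices, function(sl) {
    feats <- numeric(0)
    for (g in names(laws_map_groups)) {
      members <- laws_map_groups[[g]]
      maps <- lapply(members, function(nm)
        conv2_same(sl$img, laws_kernel(nm), pad = "replicate"))
      m <- Reduce(`+`, maps) / length(maps)
      v <- m[sl$mask]
      feats <- c(feats, map_energy(v), map_entropy(v))
    }
    setNames(feats, laws_feature_names())
  })
  average_slices(rows)
}

## ---- Discrete orthonormal Stockwell transform --------------------------

# Dyadic frequency bands over unshifted DFT indices 1..n (R, 1-based):
# {1}, {2}, {3,4}, {5..8}, ..., {n/2+1..n}. Any band partition with a
# unitary DFT inside each band yields an orthonormal transform.
dost_bands <- function(n) {
  stopifnot(n >= 2, bitwAnd(n, n - 1L) == 0)
  bands <- list(1L, 2L)
  lo <- 3L
  while (lo <= n) {
    width <- lo - 1L
    bands[[length(bands) + 1L]] <- lo:(lo + width - 1L)
    lo <- lo + width
  }
  bands
}

# 2D DOST of a (dyadic) square/rectangular matrix via FFT band partition.
dost2 <- function(img) {
  n <- nrow(img); m <- ncol(img)
  Fu <- fft(img) / sqrt(n * m)          # unitary DFT
  out <- matrix(complex(real = 0), n, m)
  for (br in dost_bands(n)) {
    for (bc in dost_bands(m)) {
      sub <- Fu[br, bc, drop = FALSE]
      out[br, bc] <- fft(sub, inverse = TRUE) / sqrt(length(sub))
    }
  }
  out
}

dost_feature_names <- function() {
  c(paste0("dost_b", 1:9, "_energy"), paste0("dost_b", 1:9, "_entropy"))
}

# Split a matrix into a 3x3 grid of near-equal blocks (row-major order).
grid3_blocks <- function(m) {
  cuts <- function(n) {
    b <- floor(n * c(0, 1, 2, 3) / 3)
    lapply(1:3, function(k) (b[k] + 1L):b[k + 1L])
  }
  rs <- cuts(nrow(m)); cs <- cuts(ncol(m))
  blocks <- list()
  for (a in 1:3) for (b in 1:3)
    blocks[[length(blocks) + 1L]] <- m[rs[[a]], cs[[b]], drop = FALSE]
  blocks
}

#' Discrete orthonormal Stockwell transform features (18)
#'
#' Each slice's mean-filled bounding box is padded to dyadic size, the 2D
#' DOST coefficient matrix is computed (FFT dyadic band partition, unitary),
#' its magnitude is split into a 3x3 grid of equal segments, and the energy
#' and entropy of each segment are averaged over slices.
#'
#' @inheritParams extract_ibhf
#' @return named numeric vector of length 18 (nine energies, nine entropies).
#' @export
extract_dost <- function(roi_values, mask = NULL) {
  prep <- roi_slices(roi_values, mask, min_pixels = if (is.null(mask)) 1L else 16L)
  if (nrow(prep$slices[[1]]$img) < 2 || ncol(prep$slices[[1]]$img) < 2)
    stop("DOST needs an ROI bounding box of at least 2x2")
  rows <- lapply(prep$slices, function(sl) {
    img <- pad_to(sl$img, next_pow2(nrow(sl$img)), next_pow2(ncol(sl$img)),
                  value = mean(sl$img[sl$mask]))
    mag <- Mod(dost2(img))
    blocks <- grid3_blocks(mag)
    en <- vapply(blocks, map_energy, 0)
    ent <- vapply(blocks, map_entropy, 0)
    setNames(c(en, ent), dost_feature_names())
  })
  average_slices(rows)
}

# Pad a matrix to (nr, nc) with a constant fill (content top-left).
pad_to <- function(m, nr, nc, value = 0) {
  out <- matrix(value, nr, nc)
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

## ---- 2D wavelet decomposition ------------------------------------------

# Daubechies-4 (4-tap) orthonormal analysis filters.
db4_lo <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
db4_hi <- rev(db4_lo) * c(1, -1, 1, -1)

# One periodized analysis step along the columns of x (length must be even):
# returns rbind(approx, detail), each half length.
dwt_step_cols <- function(x, lo, hi) {
  n <- nrow(x)
  half <- n %/% 2L
  L <- length(lo)
  a <- matrix(0, half, ncol(x)); d <- a
  for (k in seq_len(L)) {
    idx <- ((2L * seq_len(half) - 2L + (k - 1L)) %% n) + 1L
    a <- a + lo[k] * x[idx, , drop = FALSE]
    d <- d + hi[k] * x[idx, , drop = FALSE]
  }
  list(a = a, d = d)
}

# One 2D separable analysis level with periodization; input must have even,
# equal-power-of-two-friendly dimensions. Returns LL, LH, HL, HH.
dwt2_level <- function(x, lo = db4_lo, hi = db4_hi) {
  cs <- dwt_step_cols(x, lo, hi)
  rl <- dwt_step_cols(t(cs$a), lo, hi)
  rh <- dwt_step_cols(t(cs$d), lo, hi)
  list(LL = t(rl$a), LH = t(rl$d), HL = t(rh$a), HH = t(rh$d))
}

# Full multi-level 2D decomposition; returns a list per level with the
# approximation (A) and horizontal/vertical/diagonal (H, V, D) maps.
# Orientation convention: H = detail along rows (y), V = along columns (x).
dwt2_multilevel <- function(img, n_levels = 6L) {
  out <- vector("list", n_levels)
  cur <- img
  for (lev in seq_len(n_levels)) {
    if (nrow(cur) < 2 || ncol(cur) < 2)
      stop("image too small for ", n_levels, " wavelet levels")
    sub <- dwt2_level(cur)
    out[[lev]] <- list(A = sub$LL, H = sub$LH, V = sub$HL, D = sub$HH)
    cur <- sub$LL
  }
  out
}

wt_feature_names <- function(n_levels = 6L) {
  unlist(lapply(seq_len(n_levels), function(l)
    unlist(lapply(c("a", "h", "v", "d"), function(at)
      paste0("wt_l", l, "_", at, c("_energy", "_entropy"))))))
}

#' 2D wavelet-transform features (48)
#'
#' Six-level orthonormal Daubechies-4 decomposition (periodized) of each
#' slice's mean-filled bounding box padded to dyadic size (at least 64 so
#' six levels are supported); energy and entropy of the 24 attribute maps
#' (approximation, horizontal, vertical, diagonal per level), averaged over
#' slices.
#'
#' @inheritParams extract_ibhf
#' @param n_levels decomposition depth (default 6).
#' @return named numeric vector of length `8 * n_levels` (48 by default).
#' @export
extract_2dwt <- function(roi_values, mask = NULL, n_levels = 6L) {
  prep <- roi_slices(roi_values, mask, min_pixels = if (is.null(mask)) 1L else 16L)
  side_min <- 2L^n_levels
  rows <- lapply(prep$slices, function(sl) {
    nr <- max(next_pow2(nrow(sl$img)), side_min)
    nc <- max(next_pow2(ncol(sl$img)), side_min)
    img <- pad_to(sl$img, nr, nc, value = mean(sl$img[sl$mask]))
    dec <- dwt2_multilevel(img, n_levels)
    feats <- numeric(0)
    for (lev in dec) {
      for (at in c("A", "H", "V", "D")) {
        m <- lev[[at]]
        feats <- c(feats, map_energy(m), map_entropy(m))
      }
    }
    setNames(feats, wt_feature_names(n_levels))
  })
  average_slices(rows)
}

## ---- Gabor filter bank -------------------------------------------------

#' Gabor bank specification
#' @param wavelengths filter wavelengths in voxels (5 scales).
#' @param orientations angles in degrees (4 orientations).
#' @param bandwidth spatial-frequency bandwidth in octaves.
#' @return list of class `gabor_bank_spec`.
#' @export
gabor_bank_spec <- function(wavelengths = c(2, 4, 8, 16, 32),
                            orientations = c(0, 45, 90, 135),
                            bandwidth = 1) {
  structure(list(wavelengths = wavelengths, orientations = orientations,
                 bandwidth = bandwidth),
            class = "gabor_bank_spec")
}

# Complex Gabor kernel sampled on an n x m grid with wrap-around coordinates
# (centred at the origin for circular FFT convolution). The real part is
# DC-corrected so a constant image gives zero response.
gabor_kernel_grid <- function(n, m, wavelength, theta_deg, bandwidth = 1) {
  sigma <- wavelength / pi * sqrt(log(2) / 2) *
    (2^bandwidth + 1) / (2^bandwidth - 1)
  th <- theta_deg * pi / 180
  dy <- (((seq_len(n) - 1) + n %/% 2) %% n) - n %/% 2
  dx <- (((seq_len(m) - 1) + m %/% 2) %% m) - m %/% 2
  Y <- matrix(dy, n, m)
  X <- matrix(dx, n, m, byrow = TRUE)
  xr <- X * cos(th) + Y * sin(th)
  yr <- -X * sin(th) + Y * cos(th)
  env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
  re <- env * cos(2 * pi * xr / wavelength)
  im <- env * sin(2 * pi * xr / wavelength)
  # zero-DC: a constant image must give exactly zero complex response
  re <- re - env * sum(re) / sum(env)
  im <- im - env * sum(im) / sum(env)
  matrix(complex(real = re, imaginary = im), n, m)
}

# Frequency-domain Gabor bank, cached per (grid size, spec).
.gabor_cache <- new.env(parent = emptyenv())

gabor_bank_ffts <- function(n, spec) {
  key <- paste(n, paste(spec$wavelengths, collapse = ","),
               paste(spec$orientations, collapse = ","), spec$bandwidth,
               sep = "|")
  hit <- .gabor_cache[[key]]
  if (!is.null(hit)) return(hit)
  bank <- list()
  for (lam in spec$wavelengths) for (th in spec$orientations)
    bank[[length(bank) + 1L]] <-
      fft(gabor_kernel_grid(n, n, lam, th, spec$bandwidth))
  .gabor_cache[[key]] <- bank
  bank
}

gabor_feature_names <- function(spec = gabor_bank_spec()) {
  unlist(lapply(seq_along(spec$wavelengths), function(s)
    unlist(lapply(spec$orientations, function(o)
      paste0("gabor_s", s, "_o", o, c("_energy", "_entropy"))))))
}

#' Gabor filter-bank features (40)
#'
#' A 5-scale x 4-orientation complex Gabor bank (20 filters, zero-DC) is
#' applied to each slice's mean-filled bounding box by circular FFT
#' convolution; the energy and entropy of each magnitude response map,
#' pooled over in-mask pixels, are averaged over slices.
#'
#' @inheritParams extract_ibhf
#' @param spec a [gabor_bank_spec()].
#' @param pad_size FFT grid side; fixed (default 64) so the effective bank
#'   is identical for every ROI size, grown to the next power of two only
#'   when the bounding box exceeds it.
#' @return named numeric vector of length 40.
#' @export
extract_2dgf <- function(roi_values, mask = NULL, spec = gabor_bank_spec(),
                         pad_size = 64L) {
  prep <- roi_slices(roi_values, mask, min_pixels = if (is.null(mask)) 1L else 16L)
  h <- nrow(prep$slices[[1]]$img); w <- ncol(prep$slices[[1]]$img)
  n <- max(as.integer(pad_size), next_pow2(max(h, w)))
  bank <- gabor_bank_ffts(n, spec)
  rows <- lapply(prep$slices, function(sl) {
    img <- pad_to(sl$img, n, n, value = mean(sl$img[sl$mask]))
    img_f <- fft(img)
    feats <- numeric(0)
    for (kf in bank) {
      resp <- Mod(fft(img_f * kf, inverse = TRUE) / length(img))
      v <- resp[seq_len(h), seq_len(w)][sl$mask]
      feats <- c(feats, map_energy(v), map_entropy(v))
    }
    setNames(feats, gabor_feature_names(spec))
  })
  average_slices(rows)
}
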