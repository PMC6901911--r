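# Shared numeric helpers: map summaries, 2D convolution, moments.
# Conventions used across every feature family:
#   energy(map)  = mean of squared values
#   entropy(map) = Shannon entropy, log base 2, of a 256-bin min-max histogram

#' Mean-square energy of a numeric map
#' @param x numeric vector, matrix or array.
#' @return scalar mean of squared values.
#' @keywords internal
map_energy <- function(x) mean(as.numeric(x)^2)

#' Shannon entropy (bits) of a histogram of map values
#'
#' Values are binned into `n_bins` equal-width bins spanning their min-max
#' range; a constant map has entropy 0 by convention.
#' @param x numeric values.
#' @param n_bins number of histogram bins.
#' @return entropy in bits.
#' @keywords internal
map_entropy <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (!all(is.finite(rng)) || rng[1] == rng[2]) return(0)
  idx <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L, n_bins)
  p <- tabulate(idx, nbins = n_bins)
  p <- p[p > 0] / length(x)
  -sum(p * log2(p))
}

shannon_probs <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Central moment of order k (denominator n, population convention)
central_moment <- function(x, k) mean((x - mean(x))^k)

# Skewness/kurtosis with the zero-variance -> 0 convention
sample_skewness <- function(x) {
  m2 <- central_moment(x, 2)
  if (m2 <= 0) return(0)
  central_moment(x, 3) / m2^1.5
}

sample_kurtosis <- function(x) {
  m2 <- central_moment(x, 2)
  if (m2 <= 0) return(0)
  central_moment(x, 4) / m2^2
}

#' 2D "same" convolution (correlation with a flipped kernel)
#'
#' Direct spatial implementation; `pad = "zero"` pads with zeros,
#' `pad = "replicate"` extends the nearest edge value (so zero-sum kernels
#' annihilate constant images everywhere, not just in the interior).
#' Convolution orientation: output(i,j) = sum_k im(i+k) * kern(rev(k)),
#' matching the usual conv2(im, k, "same").
#' @keywords internal
conv2_same <- function(im, kern, pad = c("zero", "replicate")) {
  pad <- match.arg(pad)
  kr <- nrow(kern); kc <- ncol(kern)
  pr <- (kr - 1L) %/% 2L; pc <- (kc - 1L) %/% 2L
  nr <- nrow(im); nc <- ncol(im)
  if (pad == "zero") {
    pad_m <- matrix(0, nr + kr - 1L, nc + kc - 1L)
    pad_m[(pr + 1L):(pr + nr), (pc + 1L):(pc + nc)] <- im
  } else {
    ri <- pmin(pmax(seq_len(nr + kr - 1L) - pr, 1L), nr)
    ci <- pmin(pmax(seq_len(nc + kc - 1L) - pc, 1L), nc)
    pad_m <- im[ri, ci, drop = FALSE]
  }
  pad <- pad_m
  out <- matrix(0, nr, nc)
  kflip <- kern[kr:1L, kc:1L, drop = FALSE]
  for (a in seq_len(kr)) {
    for (b in seq_len(kc)) {
      w <- kflip[a, b]
      if (w != 0) out <- out + w * pad[a:(a + nr - 1L), b:(b + nc - 1L)]
    }
  }
  out
}

# Circular (FFT) convolution of an image with a centred kernel of the same
# size; used by the Gabor bank where the kernels are large and smooth.
conv2_circular_fft <- function(im, kern_f) {
  Re_im <- fft(fft(im) * kern_f, inverse = TRUE) / length(im)
  Re_im
}

# Frequency response of a centred spatial kernel embedded in an n x m grid.
kernel_fft <- function(kern, n, m) {
  big <- matrix(0, n, m)
  kr <- nrow(kern); kc <- ncol(kern)
  # place kernel centre at (1,1) with wrap-around so convolution is centred
  ri <- ((seq_len(kr) - (kr + 1L) %/% 2L) %% n) + 1L
  ci <- ((seq_len(kc) - (kc + 1L) %/% 2L) %% m) + 1L
  big[ri, ci] <- big[ri, ci] + kern
  fft(big)
}

next_pow2 <- function(n) 2L^ceiling(log2(max(n, 1L)))

# Bounding box of TRUE voxels in a 3D logical array; list of index ranges.
mask_bbox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0) stop("mask is empty")
  list(z = range(w[, 1]), y = range(w[, 2]), x = range(w[, 3]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
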