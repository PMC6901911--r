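# Intensity-histogram features and the local binary pattern family.

#' Intensity-based histogram features (9)
#'
#' Computed on the pooled in-mask voxel intensities: mean, SD (population),
#' skewness, kurtosis (non-excess), histogram entropy (256 bins, bits), and
#' central moments of order 3-6. Zero-variance skewness/kurtosis are 0 by
#' convention.
#'
#' @param roi_values 2D matrix, 3D volume, or numeric vector of intensities.
#' @param mask optional binary mask (same shape as a matrix/volume input).
#' @return named numeric vector of length 9.
#' @export
extract_ibhf <- function(roi_values, mask = NULL) {
  x <- if (is.null(dim(roi_values))) as.numeric(roi_values)
       else {
         v <- as_volume(roi_values)
         m <- if (is.null(mask)) array(TRUE, dim(v)) else as_volume(mask) > 0
         v[m]
       }
  if (length(x) < 2) stop("IBHF needs at least 2 voxels")
  c(ibhf_mean = mean(x),
    ibhf_sd = sqrt(central_moment(x, 2)),
    ibhf_skewness = sample_skewness(x),
    ibhf_kurtosis = sample_kurtosis(x),
    ibhf_entropy = map_entropy(x),
    ibhf_cm3 = central_moment(x, 3),
    ibhf_cm4 = central_moment(x, 4),
    ibhf_cm5 = central_moment(x, 5),
    ibhf_cm6 = central_moment(x, 6))
}

# 8-neighbour LBP code map (radius 1) of a single 2D image; codes on the
# interior grid. Bit k set when neighbour_k >= centre; neighbour order
# E, NE, N, NW, W, SW, S, SE (counter-clockwise from east).
lbp_code_map <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 3 || nc < 3) stop("LBP needs a bounding box of at least 3x3")
  ctr <- img[2:(nr - 1), 2:(nc - 1)]
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  code <- matrix(0L, nr - 2L, nc - 2L)
  for (k in seq_along(offs)) {
    dy <- offs[[k]][1]; dx <- offs[[k]][2]
    nb <- img[(2 + dy):(nr - 1 + dy), (2 + dx):(nc - 1 + dx)]
    code <- code + as.integer(nb >= ctr) * 2L^(k - 1L)
  }
  code
}

#' Local binary pattern features (6)
#'
#' An 8-neighbourhood (radius 1) LBP code map is computed per slice on the
#' mean-filled bounding box; energy, entropy (over the 256 discrete codes),
#' mean, SD, skewness and kurtosis of the in-mask codes are averaged across
#' slices.
#'
#' @inheritParams extract_ibhf
#' @return named numeric vector of length 6.
#' @export
extract_lbp <- function(roi_values, mask = NULL) {
  prep <- roi_slices(roi_values, mask, min_pixels = if (is.null(mask)) 1L else 16L)
  rows <- lapply(prep$slices, function(sl) {
    codes <- lbp_code_map(sl$img)
    keep <- sl$mask[2:(nrow(sl$mask) - 1), 2:(ncol(sl$mask) - 1), drop = FALSE]
    x <- as.numeric(codes[keep])
    if (length(x) == 0) x <- as.numeric(codes)
    p <- tabulate(as.integer(x) + 1L, nbins = 256L) / length(x)
    c(lbp_energy = mean(x^2),
      lbp_entropy = shannon_probs(p),
      lbp_mean = mean(x),
      lbp_sd = sqrt(central_moment(x, 2)),
      lbp_skewness = sample_skewness(x),
      lbp_kurtosis = sample_kurtosis(x))
  })
  average_slices(rows)
}
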