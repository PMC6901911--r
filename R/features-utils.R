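# ROI preparation and gray-level quantization shared by the texture families.

#' Quantize ROI intensities to integer gray levels
#'
#' Linear min-max mapping of the supplied values onto `{0, ..., 2^bit_depth - 1}`.
#' A constant ROI maps to all zeros and is flagged via the `"constant"`
#' attribute.
#'
#' @param roi_values numeric vector/matrix/array of intensities.
#' @param bit_depth bits of quantization, 3..8 (default 8).
#' @param range optional c(min, max) mapping range; defaults to the data range.
#' @return integer object of the same shape, levels in `0..2^bit_depth - 1`,
#'   with attribute `constant` (logical).
#' @export
quantize <- function(roi_values, bit_depth = 8L, range = NULL) {
  stopifnot(bit_depth >= 3, bit_depth <= 8)
  n_levels <- 2L^as.integer(bit_depth)
  v <- as.numeric(roi_values)
  rng <- range %||% base::range(v)
  const <- rng[1] == rng[2]
  if (const) {
    lev <- rep(0L, length(v))
  } else {
    lev <- pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * n_levels), n_levels - 1L)
    lev <- as.integer(pmax(lev, 0L))
  }
  out <- roi_values
  out[] <- lev
  storage.mode(out) <- "integer"
  attr(out, "constant") <- const
  attr(out, "n_levels") <- n_levels
  out
}

# Promote a 2D matrix to a one-slice (z, y, x) volume.
as_volume <- function(x) {
  if (is.matrix(x)) array(x, c(1L, nrow(x), ncol(x))) else x
}

# Prepare per-slice ROI views: for every slice holding at least
# `min_pixels` in-mask voxels, crop to the in-plane bounding box of the 3D
# mask and replace out-of-mask pixels by the slice's in-mask mean.
# Returns list(slices = list(img, mask), values = pooled in-mask values).
roi_slices <- function(volume, mask = NULL, min_pixels = 16L) {
  volume <- as_volume(volume)
  if (is.null(mask)) mask <- array(TRUE, dim(volume))
  mask <- as_volume(mask) > 0
  stopifnot(identical(dim(volume), dim(mask)))
  if (!any(mask)) stop("ROI mask is empty")
  bb <- mask_bbox(mask)
  ys <- bb$y[1]:bb$y[2]; xs <- bb$x[1]:bb$x[2]
  slices <- list()
  for (z in bb$z[1]:bb$z[2]) {
    msl <- mask[z, ys, xs, drop = TRUE]
    if (!is.matrix(msl)) msl <- matrix(msl, length(ys), length(xs))
    if (sum(msl) < min_pixels) next
    img <- volume[z, ys, xs, drop = TRUE]
    if (!is.matrix(img)) img <- matrix(img, length(ys), length(xs))
    img[!msl] <- mean(img[msl])
    slices[[length(slices) + 1L]] <- list(img = img, mask = msl)
  }
  if (length(slices) == 0)
    stop("no slice holds the minimum of ", min_pixels, " in-mask pixels")
  list(slices = slices, values = volume[mask])
}

# Average a per-slice feature matrix (slices x features) into one vector.
average_slices <- function(rows) {
  m <- do.call(rbind, rows)
  colMeans(m)
}
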