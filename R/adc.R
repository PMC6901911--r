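# ADC map construction and NT-mean intensity harmonization.

#' Fit an ADC map by log-linear regression over b-values
#'
#' Per voxel, the mono-exponential model `S(b) = S0 exp(-b * ADC)` is fit by
#' ordinary least squares of `log S` on `b`; the ADC is the negated slope.
#' With exactly two b-values this reduces to `log(S1/S2) / (b2 - b1)`.
#' Voxels with any non-positive signal cannot be log-transformed; they get
#' ADC 0 and are flagged.
#'
#' @param dwi_volumes list of same-shape volumes, one per b-value.
#' @param b_values numeric, same length as `dwi_volumes`, distinct.
#' @return ADC volume (mm^2/s when b is s/mm^2) with attribute
#'   `qc_nonpositive`: logical volume flagging clamped voxels.
#' @export
fit_adc <- function(dwi_volumes, b_values) {
  if (length(b_values) < 2) stop("at least 2 distinct b-values are required")
  stopifnot(length(dwi_volumes) == length(b_values),
            !anyDuplicated(b_values))
  shp <- dim(dwi_volumes[[1]])
  sig <- vapply(dwi_volumes, function(v) {
    stopifnot(identical(dim(v), shp))
    as.numeric(v)
  }, numeric(prod(shp)))                       # voxels x b
  bad <- rowSums(sig <= 0) > 0
  logs <- log(pmax(sig, .Machine$double.eps))
  b <- as.numeric(b_values)
  bc <- b - mean(b)
  # OLS slope of log S on b, vectorised over voxels
  slope <- (logs %*% bc) / sum(bc^2)
  adc <- -as.numeric(slope)
  adc[bad] <- 0
  out <- array(adc, shp)
  attr(out, "qc_nonpositive") <- array(bad, shp)
  out
}

#' Harmonize a volume by its contralateral normal-tissue mean
#'
#' Divides all intensities by the mean over the NT mask, cancelling any
#' global scanner gain so that cross-scanner intensities become comparable.
#'
#' @param volume scalar volume.
#' @param dil_mask,nt_mask binary volumes aligned to `volume`; only
#'   `nt_mask` enters the normalisation, `dil_mask` is accepted for
#'   interface symmetry.
#' @return harmonized volume (NT mean exactly 1).
#' @export
harmonize <- function(volume, dil_mask = NULL, nt_mask) {
  stopifnot(identical(dim(volume), dim(nt_mask)))
  if (!any(nt_mask)) stop("NT mask is empty")
  m <- mean(volume[nt_mask > 0])
  if (!is.finite(m) || m == 0) stop("NT mean is zero; cannot harmonize")
  volume / m
}
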