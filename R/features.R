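# Canonical 168-feature radiomics descriptor and cohort-level extraction.

#' Canonical radiomics feature names (168)
#'
#' Fixed ordering: IBHF (9), GLRL (7), LAWS (18), DOST (18), LBP (6),
#' 2DWT (48), 2DGF (40), GLCM (22).
#' @return character vector of length 168.
#' @export
feature_names <- function() {
  c(names(extract_ibhf(c(0, 1))),
    glrl_feature_names(),
    laws_feature_names(),
    dost_feature_names(),
    c("lbp_energy", "lbp_entropy", "lbp_mean", "lbp_sd",
      "lbp_skewness", "lbp_kurtosis"),
    wt_feature_names(),
    gabor_feature_names(),
    glcm_feature_names())
}

#' Feature category of each canonical feature
#' @return character vector of length 168 with the 8 category labels.
#' @export
feature_categories <- function() {
  rep(c("IBHF", "GLRL", "LAWS", "DOST", "LBP", "2DWT", "2DGF", "GLCM"),
      times = c(9, 7, 18, 18, 6, 48, 40, 22))
}

#' Extract the full 168-feature radiomics vector for one ROI
#'
#' Concatenates the eight category extractors in canonical order. The input
#' volume is expected to be harmonized already (see [harmonize()]).
#'
#' @param volume 3D volume (z, y, x) or a 2D matrix (treated as one slice).
#' @param mask binary mask of the ROI (same shape); `NULL` means all voxels.
#' @param modality optional label stored as an attribute.
#' @return named numeric vector of length 168.
#' @export
extract_all <- function(volume, mask = NULL, modality = NULL) {
  run <- function(tag, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("feature category %s failed: %s", tag, conditionMessage(e)),
           call. = FALSE))
  }
  out <- c(
    run("IBHF", function() extract_ibhf(volume, mask)),
    run("GLRL", function() extract_glrl(volume, mask)),
    run("LAWS", function() extract_laws(volume, mask)),
    run("DOST", function() extract_dost(volume, mask)),
    run("LBP", function() extract_lbp(volume, mask)),
    run("2DWT", function() extract_2dwt(volume, mask)),
    run("2DGF", function() extract_2dgf(volume, mask)),
    run("GLCM", function() extract_glcm(volume, mask))
  )
  stopifnot(length(out) == 168L)
  if (!is.null(modality)) attr(out, "modality") <- modality
  out
}

#' Extract feature tables for a whole cohort
#'
#' For every subject, both volumes are harmonized by the subject's NT-mean
#' and the 168-feature vector is extracted for the DIL and NT masks of each
#' modality. When DWI volumes are present the ADC map is re-fit from them by
#' log-linear regression; otherwise the stored ADC volume is used.
#'
#' @param cohort a `synth_cohort` or list of `synth_subject` objects.
#' @param harmonize_adc also apply NT-mean harmonization to the ADC map
#'   (default TRUE; set FALSE to keep ADC in physical units).
#' @param refit_adc re-derive the ADC map from DWI volumes when available.
#' @param dil_masks,nt_masks optional named lists (by subject_id) of
#'   replacement masks, e.g. perturbed contours.
#' @return tibble with columns `subject_id`, `group_tag`, `roi`
#'   (`"DIL"`/`"NT"`), `modality` (`"T2W"`/`"ADC"`) and the 168 features.
#' @export
extract_features <- function(cohort, harmonize_adc = TRUE, refit_adc = TRUE,
                             dil_masks = NULL, nt_masks = NULL) {
  rows <- list()
  for (s in cohort) {
    dil <- dil_masks[[s$subject_id]] %||% s$dil_mask
    nt <- nt_masks[[s$subject_id]] %||% s$nt_mask
    adc <- if (refit_adc && !is.null(s$dwi_volumes)) {
      fit_adc(s$dwi_volumes, s$b_values)
    } else s$adc_volume
    vols <- list(
      T2W = harmonize(s$t2w_volume, dil, nt),
      ADC = if (harmonize_adc) harmonize(adc, dil, nt) else adc
    )
    for (modality in names(vols)) {
      for (roi in c("DIL", "NT")) {
        mask <- if (roi == "DIL") dil else nt
        fv <- extract_all(vols[[modality]], mask, modality)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject_id = s$subject_id, group_tag = s$group_tag,
          roi = roi, modality = modality,
          !!!as.list(fv))
      }
    }
  }
  dplyr::bind_rows(rows)
}
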