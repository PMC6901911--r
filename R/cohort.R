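# Synthetic paired-modality cohort generation.
#
# Each subject carries co-registered pseudo-T2W and pseudo-ADC volumes with a
# hypo-intense, texturally distinct spherical lesion (DIL) and a mirrored
# contralateral normal-tissue (NT) control region. Textures are Gaussian
# random fields: white noise smoothed in-plane with a Gaussian kernel whose
# width sets the correlation length, rescaled to unit marginal SD, then
# shifted/scaled to tissue mean and SD. A shared latent noise field couples
# the two modalities.

#' Configuration for a synthetic paired-modality cohort
#'
#' Defaults define the reference study conditions used throughout the
#' package: 117 subjects, 64 x 64 in-plane grids with 12 slices, an in-plane
#' DIL radius of 7 voxels (ellipsoidal, 2-slice z semi-axis), and a strong
#' lesion contrast (`effect_size = 2`). `effect_size` scales both the
#' hypo-intensity of the lesion (in NT-SD units) and its texture-correlation
#' lengthening; `effect_size = 0` makes DIL and NT draws from the identical
#' generative process.
#'
#' @param n_subjects number of simulated patients.
#' @param volume_shape integer vector (z, y, x) of voxels per axis.
#' @param voxel_spacing numeric (z, y, x) mm per voxel.
#' @param dil_radius in-plane lesion radius, voxels.
#' @param dil_z_radius lesion semi-axis along z, slices.
#' @param effect_size dimensionless lesion contrast; 0 gives a null cohort.
#' @param texture_params list with per-modality NT parameters
#'   (`mean`, `sd`, `corr_length`); see defaults.
#' @param cross_modality_coupling fraction in \[0, 1\] of noise variance
#'   shared between modalities.
#' @param b_values diffusion weightings, s/mm^2.
#' @param s0 baseline diffusion signal at b = 0.
#' @param with_dwi simulate per-b-value DWI volumes (mono-exponential decay).
#' @param dwi_noise_sd Gaussian noise SD added to DWI signals (0 = noiseless).
#' @param group_tag cohort label attached to every subject ("A"/"B" style).
#' @param seed RNG seed; cohorts are bit-reproducible given the seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 117L,
                          volume_shape = c(12L, 64L, 64L),
                          voxel_spacing = c(3, 1, 1),
                          dil_radius = 7,
                          dil_z_radius = 2,
                          effect_size = 2,
                          texture_params = list(
                            t2w = list(mean = 100, sd = 15, corr_length = 1.5),
                            adc = list(mean = 1.8e-3, sd = 2.5e-4, corr_length = 1.5)
                          ),
                          cross_modality_coupling = 0.6,
                          b_values = c(50, 400, 800),
                          s0 = 1000,
                          with_dwi = TRUE,
                          dwi_noise_sd = 0,
                          group_tag = "A",
                          seed = 1L) {
  stopifnot(n_subjects >= 1, effect_size >= 0,
            length(volume_shape) == 3, all(volume_shape > 0),
            all(voxel_spacing > 0), dil_radius > 0, dil_z_radius > 0,
            cross_modality_coupling >= 0, cross_modality_coupling <= 1,
            all(b_values >= 0), !anyDuplicated(b_values))
  for (m in c("t2w", "adc")) {
    tp <- texture_params[[m]]
    stopifnot(!is.null(tp$mean), tp$sd > 0, tp$corr_length > 0)
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         volume_shape = as.integer(volume_shape),
         voxel_spacing = as.numeric(voxel_spacing),
         dil_radius = dil_radius, dil_z_radius = dil_z_radius,
         effect_size = effect_size, texture_params = texture_params,
         cross_modality_coupling = cross_modality_coupling,
         b_values = as.numeric(b_values), s0 = s0,
         with_dwi = isTRUE(with_dwi), dwi_noise_sd = dwi_noise_sd,
         group_tag = group_tag, seed = as.integer(seed)),
    class = "cohort_config")
}

# In-plane Gaussian smoothing, slice by slice, via separable direct
# convolution (zero padding at edges; fields are restandardised afterwards).
gauss_smooth_inplane <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  kc <- matrix(k, ncol = 1)
  kr <- matrix(k, nrow = 1)
  out <- vol
  for (z in seq_len(dim(vol)[1])) {
    out[z, , ] <- conv2_same(conv2_same(vol[z, , ], kc), kr)
  }
  out
}

# Smooth white noise to a target correlation length and restandardise to
# unit marginal SD (estimated over the volume).
textured_field <- function(noise, corr_length) {
  f <- gauss_smooth_inplane(noise, corr_length)
  s <- sd(as.numeric(f))
  if (s > 0) f <- f / s
  f
}

ellipsoid_mask <- function(shape, centre, r_inplane, r_z) {
  z <- slice.index(array(0, shape), 1)
  y <- slice.index(array(0, shape), 2)
  x <- slice.index(array(0, shape), 3)
  ((z - centre[1]) / r_z)^2 + ((y - centre[2]) / r_inplane)^2 +
    ((x - centre[3]) / r_inplane)^2 <= 1
}

mirror_x <- function(mask) {
  nx <- dim(mask)[3]
  mask[, , nx:1, drop = FALSE]
}

generate_subject <- function(config, subject_id) {
  shp <- config$volume_shape
  nz <- shp[1]; ny <- shp[2]; nx <- shp[3]
  eff <- config$effect_size

  centre <- c(ceiling(nz / 2), ceiling(ny / 2), round(nx * 0.3))
  dil_mask <- ellipsoid_mask(shp, centre, config$dil_radius, config$dil_z_radius)
  nt_mask <- mirror_x(dil_mask)
  if (any(dil_mask & nt_mask))
    stop("dil_radius too large for volume_shape: DIL and mirrored NT masks overlap")
  if (!any(dil_mask)) stop("dil_radius too small: empty DIL mask")

  shared_bg <- array(rnorm(prod(shp)), shp)
  shared_dil <- array(rnorm(prod(shp)), shp)
  c2 <- config$cross_modality_coupling

  vols <- list()
  for (m in c("t2w", "adc")) {
    tp <- config$texture_params[[m]]
    own_bg <- array(rnorm(prod(shp)), shp)
    own_dil <- array(rnorm(prod(shp)), shp)
    noise_bg <- sqrt(c2) * shared_bg + sqrt(1 - c2) * own_bg
    noise_dil <- sqrt(c2) * shared_dil + sqrt(1 - c2) * own_dil

    bg <- textured_field(noise_bg, tp$corr_length)
    vol <- tp$mean + tp$sd * bg
    if (eff > 0) {
      # lesion: hypo-intense by eff NT-SDs, correlation length +50% per unit
      dil_field <- textured_field(noise_dil, tp$corr_length * (1 + 0.5 * eff))
      dil_mean <- tp$mean - eff * tp$sd
      vol[dil_mask] <- (dil_mean + tp$sd * dil_field)[dil_mask]
    }
    vols[[m]] <- vol
  }
  # ADC must stay positive for the diffusion model
  vols$adc <- pmax(vols$adc, 1e-6)

  dwi <- NULL
  if (config$with_dwi) {
    s0_vol <- array(config$s0, shp)
    dwi <- simulate_dwi(vols$adc, s0_vol, config$b_values,
                        noise_sd = config$dwi_noise_sd)
  }

  structure(
    list(subject_id = subject_id,
         t2w_volume = vols$t2w, adc_volume = vols$adc,
         dwi_volumes = dwi, b_values = config$b_values,
         dil_mask = dil_mask, nt_mask = nt_mask,
         voxel_spacing = config$voxel_spacing,
         group_tag = config$group_tag),
    class = "synth_subject")
}

#' Generate a synthetic paired-modality cohort
#'
#' Deterministic given `config$seed`. Each subject receives fresh noise
#' fields; with `effect_size = 0` the DIL and NT regions are draws from the
#' identical generative process (null cohort).
#'
#' @param config a [cohort_config()].
#' @return list of `synth_subject` objects, class `synth_cohort`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 2, seed = 7))
#' length(cohort)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, {
    subjects <- lapply(seq_len(config$n_subjects), function(i) {
      generate_subject(config, sprintf("%s%03d", config$group_tag, i))
    })
  })
  structure(subjects, class = "synth_cohort", config = config)
}

#' Simulate diffusion-weighted volumes from a true ADC map
#'
#' Mono-exponential decay `S(b) = S0 exp(-b * ADC)`, optionally with additive
#' Gaussian noise.
#'
#' @param true_adc_volume ADC map, mm^2/s; must be non-negative.
#' @param s0_volume baseline signal at b = 0, same shape.
#' @param b_values distinct non-negative b-values, s/mm^2.
#' @param noise_sd additive Gaussian noise SD (0 = noiseless).
#' @return named list of volumes, one per b-value (`b50`, `b400`, ...).
#' @export
simulate_dwi <- function(true_adc_volume, s0_volume, b_values, noise_sd = 0) {
  stopifnot(identical(dim(true_adc_volume), dim(s0_volume)),
            all(b_values >= 0), !anyDuplicated(b_values))
  if (any(true_adc_volume < 0)) stop("negative ADC voxels are not physical")
  out <- lapply(b_values, function(b) {
    s <- s0_volume * exp(-b * true_adc_volume)
    if (noise_sd > 0) s <- s + array(rnorm(length(s), sd = noise_sd), dim(s))
    s
  })
  names(out) <- paste0("b", b_values)
  out
}

#' Analytically tractable 2D fixture images
#'
#' Small deterministic images used to unit-test the feature extractors.
#'
#' @param kind one of `"constant"`, `"checkerboard"`, `"ramp"`,
#'   `"single_run_rows"`, `"impulse"`, `"two_level"`.
#' @param size side length in pixels.
#' @param value level used by `"constant"` and `"single_run_rows"`.
#' @return a `size` x `size` numeric matrix.
#' @export
make_fixture_image <- function(kind, size = 8L, value = 1) {
  size <- as.integer(size)
  stopifnot(size >= 1)
  switch(kind,
    constant = matrix(value, size, size),
    checkerboard = outer(seq_len(size), seq_len(size),
                         function(i, j) (i + j) %% 2),
    ramp = matrix(rep(seq_len(size), each = size) - 1, size, size),
    single_run_rows = matrix(value, size, size),
    impulse = {
      m <- matrix(0, size, size)
      m[(size + 1L) %/% 2L, (size + 1L) %/% 2L] <- 1
      m
    },
    two_level = matrix(rep(c(0, 1), each = ceiling(size * size / 2))[
      seq_len(size * size)], size, size),
    stop("unknown fixture kind: ", kind)
  )
}

#' Cohort manifest as a tibble
#' @param x a `synth_cohort`.
#' @param ... unused.
#' @return tibble with one row per subject.
#' @method as_tibble synth_cohort
#' @export
as_tibble.synth_cohort <- function(x, ...) {
  tibble::tibble(
    subject_id = vapply(x, `[[`, "", "subject_id"),
    group_tag = vapply(x, `[[`, "", "group_tag"),
    n_dil_voxels = vapply(x, function(s) sum(s$dil_mask), 0),
    n_nt_voxels = vapply(x, function(s) sum(s$nt_mask), 0)
  )
}

#' @export
print.synth_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<synth_cohort> %d subjects, volume %s, effect_size %.2f, seed %d\n",
              length(x), paste(cfg$volume_shape, collapse = "x"),
              cfg$effect_size, cfg$seed))
  invisible(x)
}

#' Write a cohort to NIfTI volumes plus a subjects.csv manifest
#'
#' @param cohort a `synth_cohort`.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest tibble with file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(s) {
    paths <- c(t2w = file.path(dir, paste0(s$subject_id, "_t2w.nii.gz")),
               adc = file.path(dir, paste0(s$subject_id, "_adc.nii.gz")),
               dil = file.path(dir, paste0(s$subject_id, "_dil.nii.gz")),
               nt = file.path(dir, paste0(s$subject_id, "_nt.nii.gz")))
    RNifti::writeNifti(RNifti::asNifti(s$t2w_volume), paths["t2w"])
    RNifti::writeNifti(RNifti::asNifti(s$adc_volume), paths["adc"])
    RNifti::writeNifti(RNifti::asNifti(s$dil_mask * 1L), paths["dil"])
    RNifti::writeNifti(RNifti::asNifti(s$nt_mask * 1L), paths["nt"])
    tibble::tibble(subject_id = s$subject_id, group_tag = s$group_tag,
                   t2w_path = paths[["t2w"]], adc_path = paths[["adc"]],
                   dil_path = paths[["dil"]], nt_path = paths[["nt"]])
  })
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(dir, "subjects.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort previously written with [write_cohort()]
#' @param dir directory containing `subjects.csv` and NIfTI files.
#' @return a `synth_cohort` (without DWI volumes).
#' @export
read_cohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "subjects.csv"), stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    structure(
      list(subject_id = row$subject_id,
           t2w_volume = array(as.numeric(RNifti::readNifti(row$t2w_path)),
                              dim(RNifti::readNifti(row$t2w_path))),
           adc_volume = array(as.numeric(RNifti::readNifti(row$adc_path)),
                              dim(RNifti::readNifti(row$adc_path))),
           dwi_volumes = NULL, b_values = NULL,
           dil_mask = array(as.numeric(RNifti::readNifti(row$dil_path)) > 0.5,
                            dim(RNifti::readNifti(row$dil_path))),
           nt_mask = array(as.numeric(RNifti::readNifti(row$nt_path)) > 0.5,
                           dim(RNifti::readNifti(row$nt_path))),
           voxel_spacing = NULL, group_tag = row$group_tag),
      class = "synth_subject")
  })
  structure(subjects, class = "synth_cohort")
}
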