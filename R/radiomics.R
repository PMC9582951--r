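#' Z-score intensity normalization of a volume
#'
#' Centres an image at its mean and scales by the standard deviation of all
#' gray values in the image (whole volume, not mask-restricted; population
#' SD). Applied to relative-intensity modalities such as post-contrast T1
#' before feature extraction, so that features are invariant to the arbitrary
#' per-scan affine intensity scale; quantitative maps (ADC) are left
#' untouched.
#'
#' @param volume Numeric array.
#' @return Array of the same shape with mean 0, SD 1 over all voxels.
#' @export
normalize_intensity <- function(volume) {
  mu <- mean(volume)
  s <- sqrt(mean((volume - mu)^2))
  if (s == 0) rp_abort("cannot normalize a constant volume (zero SD)")
  (volume - mu) / s
}

#' Extract the per-patient radiomic feature block
#'
#' Runs the 91-feature engine on each patient's volume restricted to its VOI
#' mask. For T1C the volume is intensity-normalized first (see
#' [normalize_intensity()]); ADC maps are quantitative and used as-is.
#'
#' @param cohort An `rp_cohort` (or any list with the same `patients` layout).
#' @param modality `"ADC"` or `"T1C"`.
#' @param config Feature-engine configuration; default fixed bin width 25 for
#'   ADC and, because normalized T1C lives on a unit scale, bin width 0.1
#'   for T1C.
#' @return A tibble: `patient_id`, `mean_adc` (ADC only, the in-VOI mean used
#'   by the preliminary cellularity analysis), `mask_voxels`, then the 91
#'   prefixed feature columns.
#' @export
extract_radiomics <- function(cohort, modality = c("ADC", "T1C"),
                              config = NULL) {
  modality <- match.arg(modality)
  if (is.null(config)) {
    config <- if (modality == "ADC") fe_config("width", bin_width = 25)
      else fe_config("width", bin_width = 0.1)
  }
  rows <- purrr::map(cohort$patients, function(p) {
    v <- p$volumes[[modality]]
    if (is.null(v)) rp_abort("patient ", p$id, " has no ", modality, " volume")
    img <- if (modality == "T1C") normalize_intensity(v$image) else v$image
    fv <- extract_features(img, v$mask, config, spacing = v$spacing)
    names(fv) <- paste(modality, names(fv), sep = "_")
    out <- tibble::tibble(patient_id = p$id, mask_voxels = sum(v$mask))
    if (modality == "ADC") out$mean_adc <- mean(v$image[v$mask])
    dplyr::bind_cols(out, tibble::as_tibble_row(fv))
  })
  dplyr::bind_rows(rows)
}
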