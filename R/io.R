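#' Write a cohort to disk
#'
#' Persists a synthetic (or assembled) cohort in interchange formats:
#' per-patient NIfTI volumes and masks (`<id>_<modality>.nii.gz`,
#' `<id>_<modality>_mask.nii.gz`), per-slide tab-delimited detection tables,
#' a `roi.json` per patient, and cohort-level `ground_truth.json` and
#' `config.json`.
#'
#' @param cohort An `rp_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$patients) {
    pd <- file.path(dir, p$id)
    dir.create(pd, showWarnings = FALSE)
    for (mod in names(p$volumes)) {
      v <- p$volumes[[mod]]
      RNifti::writeNifti(RNifti::asNifti(v$image, pixdim = v$spacing),
                         file.path(pd, paste0(p$id, "_", mod, ".nii.gz")))
      RNifti::writeNifti(RNifti::asNifti(v$mask * 1L, pixdim = v$spacing),
                         file.path(pd, paste0(p$id, "_", mod, "_mask.nii.gz")))
    }
    for (s in seq_along(p$slides)) {
      write_detections(p$slides[[s]],
                       file.path(pd, sprintf("%s_S%d_detections.tsv", p$id, s)))
    }
    jsonlite::write_json(p$roi, file.path(pd, "roi.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(latent_scores = gt$latent_scores,
         coupled_pairs = gt$coupled_pairs,
         null_pairs = gt$null_pairs,
         all_null = gt$all_null),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(cohort$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort back from disk
#'
#' Inverse of [write_cohort()]: reconstructs the in-memory cohort object
#' (volumes as plain arrays, detection tables as tibbles). Ground truth is
#' loaded only if present — analysis stages never require it.
#'
#' @param dir Directory written by [write_cohort()].
#' @return An `rp_cohort`.
#' @export
read_cohort <- function(dir) {
  cfgp <- file.path(dir, "config.json")
  if (!file.exists(cfgp)) rp_abort("no config.json under ", dir)
  cfg <- jsonlite::read_json(cfgp, simplifyVector = TRUE)
  ids <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  patients <- purrr::map(ids, function(id) {
    pd <- file.path(dir, id)
    roi <- jsonlite::read_json(file.path(pd, "roi.json"), simplifyVector = TRUE)
    vols <- list()
    for (mod in c("ADC", "T1C")) {
      f <- file.path(pd, paste0(id, "_", mod, ".nii.gz"))
      if (!file.exists(f)) next
      img <- RNifti::readNifti(f)
      msk <- RNifti::readNifti(file.path(pd, paste0(id, "_", mod, "_mask.nii.gz")))
      vols[[mod]] <- list(image = array(as.numeric(img), dim(img)),
                          mask = array(as.numeric(msk) > 0, dim(msk)),
                          spacing = RNifti::pixdim(img))
    }
    tsvs <- sort(list.files(pd, pattern = "_detections\\.tsv$", full.names = TRUE))
    list(id = id, volumes = vols,
         slides = purrr::map(tsvs, read_detections), roi = roi)
  })
  gtp <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gtp)) {
    g <- jsonlite::read_json(gtp, simplifyVector = TRUE)
    list(latent_scores = as.matrix(g$latent_scores),
         coupled_pairs = tibble::as_tibble(g$coupled_pairs),
         null_pairs = tibble::as_tibble(g$null_pairs),
         all_null = isTRUE(g$all_null))
  } else NULL
  structure(list(patients = patients, ground_truth = gt, config = cfg),
            class = "rp_cohort")
}
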