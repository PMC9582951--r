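#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end study: the simulation (or an input
#' cohort directory), feature-engine settings, the redundancy-filter
#' threshold, the significance level, density-map resolutions and the master
#' seed. All defaults are echoed into the run log so a run is fully
#' reproducible from its output directory.
#'
#' @param cohort_dir Optional directory of an existing cohort (from
#'   [write_cohort()]); when `NULL` a cohort is simulated from `simulate`.
#' @param simulate A [cohort_config()] used when `cohort_dir` is `NULL`.
#' @param filter_threshold Redundancy-filter cutoff on `|rho|`. Default 0.9.
#' @param alpha Significance level on FDR-adjusted q-values. Default 0.05.
#' @param resolutions Density-map resolutions (micrometres).
#' @param adc_config,t1c_config,density_config Feature-engine settings per
#'   image type.
#' @param seed Master seed for the analysis stages (CV folds).
#' @param write_volumes Also persist the cohort itself under the run
#'   directory. Default TRUE.
#' @return Object of class `rp_pipeline_config`.
#' @export
pipeline_config <- function(cohort_dir = NULL, simulate = cohort_config(),
                            filter_threshold = 0.9, alpha = 0.05,
                            resolutions = c(50, 100, 150, 200),
                            adc_config = fe_config("width", bin_width = 25),
                            t1c_config = fe_config("width", bin_width = 0.1),
                            density_config = fe_config("count", bin_count = 32),
                            seed = 1, write_volumes = TRUE) {
  if (filter_threshold <= 0 || filter_threshold > 1) {
    rp_abort("filter_threshold must lie in (0, 1]")
  }
  if (alpha <= 0 || alpha >= 1) rp_abort("alpha must lie in (0, 1)")
  if (any(resolutions <= 0)) rp_abort("resolutions must be positive")
  if (!is.null(cohort_dir) && !dir.exists(cohort_dir)) {
    rp_abort("cohort_dir does not exist: ", cohort_dir)
  }
  structure(
    list(cohort_dir = cohort_dir, simulate = simulate,
         filter_threshold = filter_threshold, alpha = alpha,
         resolutions = resolutions, adc_config = adc_config,
         t1c_config = t1c_config, density_config = density_config,
         seed = as.integer(seed), write_volumes = isTRUE(write_volumes)),
    class = "rp_pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Accepts a plain-text profile with any subset of the [pipeline_config()]
#' fields (nested `simulate:` block for the cohort simulation); unspecified
#' fields keep their defaults.
#'
#' @param path YAML file.
#' @return An `rp_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(cohort_config, y$simulate %||% list())
  fe_from <- function(spec, default) {
    if (is.null(spec)) return(default)
    do.call(fe_config, spec)
  }
  pipeline_config(
    cohort_dir = y$cohort_dir,
    simulate = sim,
    filter_threshold = y$filter_threshold %||% 0.9,
    alpha = y$alpha %||% 0.05,
    resolutions = unlist(y$resolutions %||% c(50, 100, 150, 200)),
    adc_config = fe_from(y$adc_config, fe_config("width", bin_width = 25)),
    t1c_config = fe_from(y$t1c_config, fe_config("width", bin_width = 0.1)),
    density_config = fe_from(y$density_config, fe_config("count", bin_count = 32)),
    seed = y$seed %||% 1,
    write_volumes = y$write_volumes %||% TRUE
  )
}

#' Run the end-to-end radiology-pathology association study
#'
#' Executes every stage in order for the two tasks (ADC vs pathomics and T1C
#' vs pathomics): cohort simulation (or loading), radiomic and pathomic
#' feature blocks, the preliminary mean-ADC cellularity analysis,
#' per-block redundancy filtering, the feature-level cross-scale screen with
#' FDR and Bayes factors, significance-filtered heatmap matrices, and
#' factor-analytic compression with factor-score cross-correlation. All
#' tables are written as CSV, models and the run log as JSON, under `out_dir`.
#' Outputs are byte-identical across runs with the same configuration and
#' seed; the analysis stages never read the simulation ground truth.
#'
#' @param config An [pipeline_config()].
#' @param out_dir Output directory (created; must be empty or absent).
#' @return Invisibly, a list with the in-memory results (`cohort`, blocks,
#'   filters, association tables, compressions, factor associations,
#'   preliminary table, paths).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  t0 <- Sys.time()
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0) {
    rp_abort("out_dir exists and is not empty: ", out_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t <- Sys.time()
    r <- tryCatch(expr, error = function(e) {
      rp_abort("stage '", name, "' failed: ", conditionMessage(e),
               class = "radiopathomics_stage_error")
    })
    rp_log("stage ", name, " done in ",
           round(as.numeric(Sys.time() - t, units = "secs"), 1), "s")
    r
  }

  # --- cohort ---------------------------------------------------------------
  cohort <- stage("cohort", {
    if (is.null(config$cohort_dir)) generate_cohort(config$simulate)
    else read_cohort(config$cohort_dir)
  })
  if (config$write_volumes && is.null(config$cohort_dir)) {
    stage("write-cohort", write_cohort(cohort, file.path(out_dir, "cohort")))
  }

  fdir <- file.path(out_dir, "features")
  adir <- file.path(out_dir, "associations")
  kdir <- file.path(out_dir, "factors")
  for (d in c(fdir, adir, kdir)) dir.create(d, showWarnings = FALSE)

  # --- feature blocks -------------------------------------------------------
  adc <- stage("radiomics-ADC",
               extract_radiomics(cohort, "ADC", config$adc_config))
  t1c <- stage("radiomics-T1C",
               extract_radiomics(cohort, "T1C", config$t1c_config))
  path_blk <- stage("pathomics",
                    pathomic_block(cohort, config$resolutions,
                                   config$density_config))
  annot <- stage("annotation", annotation_block(cohort))
  readr::write_csv(adc, file.path(fdir, "radiomics_adc.csv"), progress = FALSE)
  readr::write_csv(t1c, file.path(fdir, "radiomics_t1c.csv"), progress = FALSE)
  readr::write_csv(path_blk, file.path(fdir, "pathomics.csv"), progress = FALSE)
  readr::write_csv(annot, file.path(fdir, "annotation.csv"), progress = FALSE)

  # --- preliminary analysis -------------------------------------------------
  prelim <- stage("preliminary", preliminary_adc_analysis(adc, annot))
  readr::write_csv(prelim, file.path(adir, "preliminary_adc.csv"),
                   progress = FALSE)

  # --- redundancy filters ---------------------------------------------------
  filters <- stage("filter", list(
    ADC = correlation_filter(adc, config$filter_threshold),
    T1C = correlation_filter(t1c, config$filter_threshold),
    pathomic = correlation_filter(path_blk, config$filter_threshold)
  ))
  for (b in names(filters)) {
    readr::write_csv(
      tibble::tibble(feature = filters[[b]]$retained),
      file.path(adir, paste0("filter_retained_", tolower(b), ".csv")),
      progress = FALSE)
    readr::write_csv(filters[[b]]$removed,
      file.path(adir, paste0("filter_removed_", tolower(b), ".csv")),
      progress = FALSE)
  }

  keep_cols <- function(block, f) {
    dplyr::select(block, dplyr::any_of(rp_id_cols), dplyr::all_of(f$retained))
  }
  adc_f <- keep_cols(adc, filters$ADC)
  t1c_f <- keep_cols(t1c, filters$T1C)
  path_f <- keep_cols(path_blk, filters$pathomic)

  # --- feature-level cross-scale screens ------------------------------------
  assoc <- list()
  for (task in c("ADC", "T1C")) {
    rad <- if (task == "ADC") adc_f else t1c_f
    a <- stage(paste0("associate-", task),
               cross_correlate(rad, path_f, alpha = config$alpha))
    assoc[[task]] <- a
    readr::write_csv(a, file.path(adir, paste0(
      "associations_", tolower(task), "_pathomic.csv")), progress = FALSE)
    mats <- rp_association_matrices(a)
    hm <- filter_heatmap(mats$rho, mats$significant)
    readr::write_csv(
      tibble::as_tibble(hm, rownames = "radiomic_feature"),
      file.path(adir, paste0("heatmap_", tolower(task), "_pathomic.csv")),
      progress = FALSE)
  }

  # --- factor stage ---------------------------------------------------------
  comp <- stage("factors", list(
    ADC = compress_features(adc_f, "ADC", seed = config$seed),
    T1C = compress_features(t1c_f, "T1C", seed = config$seed),
    pathomic = compress_features(path_f, "pathomic", seed = config$seed)
  ))
  for (b in names(comp)) {
    readr::write_csv(tidy(comp[[b]]$model),
                     file.path(kdir, paste0("loadings_", tolower(b), ".csv")),
                     progress = FALSE)
    readr::write_csv(comp[[b]]$scores,
                     file.path(kdir, paste0("scores_", tolower(b), ".csv")),
                     progress = FALSE)
    jsonlite::write_json(
      as.list(glance(comp[[b]]$model)),
      file.path(kdir, paste0("model_", tolower(b), ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  fassoc <- list()
  for (task in c("ADC", "T1C")) {
    fa <- stage(paste0("factor-associate-", task),
                factor_cross_correlation(comp[[task]]$scores,
                                         comp$pathomic$scores,
                                         alpha = config$alpha))
    fassoc[[task]] <- fa
    readr::write_csv(fa, file.path(kdir, paste0(
      "factor_associations_", tolower(task), "_pathomic.csv")), progress = FALSE)
  }

  # --- run log --------------------------------------------------------------
  csvs <- sort(list.files(out_dir, pattern = "\\.csv$", recursive = TRUE))
  log <- list(
    package_version = as.character(utils::packageVersion("radiopathomics")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    alpha = config$alpha,
    filter_threshold = config$filter_threshold,
    resolutions = config$resolutions,
    simulated = is.null(config$cohort_dir),
    cohort_config = if (is.null(config$cohort_dir))
      unclass(config$simulate) else config$cohort_dir,
    n_patients = length(cohort$patients),
    stage_outputs = as.list(setNames(
      unname(tools::md5sum(file.path(out_dir, csvs))), csvs))
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  rp_log("pipeline finished in ",
         round(as.numeric(Sys.time() - t0, units = "secs"), 1), "s")

  invisible(list(cohort = cohort, radiomics = list(ADC = adc, T1C = t1c),
                 pathomics = path_blk, annotation = annot,
                 preliminary = prelim, filters = filters,
                 associations = assoc, compressions = comp,
                 factor_associations = fassoc, out_dir = out_dir))
}
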