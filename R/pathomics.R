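#' Read a cell-detection table
#'
#' Parses a tab-delimited detection export (one row per cell): columns
#' `Slide`, `Centroid X µm`, `Centroid Y µm` and the 65 measurement columns
#' of [rp_detection_schema()]. Rows containing any non-finite measurement are
#' dropped with a logged count.
#'
#' @param path Path to the TSV file.
#' @return A tibble of detections.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) rp_abort("no such detection file: ", path)
  det <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c(rp_centroid_cols, rp_detection_schema()$all)
  missing <- setdiff(required, names(det))
  if (length(missing) > 0) {
    rp_abort("detection table misses required column(s): ",
             paste(missing, collapse = ", "))
  }
  num <- det[, setdiff(required, "Slide")]
  bad <- !Reduce(`&`, lapply(num, function(col) is.finite(col)))
  if (any(bad)) {
    rp_log("dropped ", sum(bad), " detection row(s) with non-finite measurements")
    det <- det[!bad, ]
  }
  det
}

#' Write a detection table as TSV
#'
#' @param detections Detection tibble (see [read_detections()] for layout).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  readr::write_tsv(detections, path, progress = FALSE)
  invisible(path)
}

#' Aggregate detection measurements to one 65-value patient vector
#'
#' Two-level unweighted mean: per slide, the mean over its cells for each of
#' the 65 measurement columns; per patient, the mean of the slide means (a
#' slide with many cells does not dominate). Slides with zero detections are
#' excluded with a log message. `NA` Delaunay sentinels are ignored within a
#' slide.
#'
#' @param slides List of detection tibbles, one per slide.
#' @return Named numeric vector of length 65.
#' @export
aggregate_detections <- function(slides) {
  if (length(slides) == 0) rp_abort("no slides supplied")
  cols <- rp_detection_schema()$all
  means <- purrr::map(slides, function(s) {
    if (nrow(s) == 0) return(NULL)
    vapply(cols, function(cl) mean(s[[cl]], na.rm = TRUE), numeric(1))
  })
  empty <- vapply(means, is.null, logical(1))
  if (any(empty)) rp_log(sum(empty), " slide(s) with 0 detections excluded")
  means <- means[!empty]
  if (length(means) == 0) rp_abort("all slides have 0 detections")
  colMeans(do.call(rbind, means))
}

#' Slide-level annotation measurements
#'
#' Region-level summaries of one slide: nuclei count, extracellular area
#' (ROI area minus the summed cell areas), extracellular + cytoplasm area
#' (ROI area minus the summed nucleus areas), and each normalized by the ROI
#' area. Cell area per detection is reconstructed as nucleus area divided by
#' the nucleus/cell area ratio. Summed areas exceeding the ROI are clamped at
#' zero remaining space (overlapping segmentations) with a log message.
#'
#' @param detections Detection tibble for one slide.
#' @param roi_area ROI area in square micrometres (> 0).
#' @return One-row tibble with raw and normalized measurements.
#' @export
annotation_measurements <- function(detections, roi_area) {
  if (roi_area <= 0) rp_abort("roi_area must be positive")
  n <- nrow(detections)
  nuc_area <- if (n) sum(detections[["Nucleus: Area"]]) else 0
  cell_area <- if (n) {
    sum(detections[["Nucleus: Area"]] / detections[["Nucleus/Cell area ratio"]])
  } else 0
  extracellular <- roi_area - cell_area
  if (extracellular < 0) {
    rp_log("summed cell areas exceed the ROI; extracellular area clamped to 0")
    extracellular <- 0
  }
  extra_cyto <- max(roi_area - nuc_area, 0)
  tibble::tibble(
    selected_area = roi_area,
    nuclei_count = n,
    extracellular_area = extracellular,
    extracellular_cytoplasm_area = extra_cyto,
    nuclei_count_norm = n / roi_area,
    extracellular_norm = extracellular / roi_area,
    extracellular_cytoplasm_norm = extra_cyto / roi_area
  )
}

#' Build a nuclear cell-density map
#'
#' Lays a square tile grid of side `resolution` micrometres over the ROI
#' bounding box (anchored at its origin; tiles are half-open
#' `[i*r, (i+1)*r)`), counts the nuclei centroids falling in each tile, and
#' marks as valid the tiles whose centre lies inside the ROI. Counts outside
#' the valid mask are zeroed.
#'
#' @param centroids Matrix/data frame, first two columns x/y in micrometres.
#' @param roi Either a numeric vector `c(width, height)` for a rectangular
#'   ROI anchored at the origin, or a two-column polygon matrix (closed
#'   implicitly) in micrometres.
#' @param resolution Tile side in micrometres (one of 50/100/150/200 in the
#'   standard pipeline, any positive value accepted).
#' @return An object of class `rp_density_map`: list with `counts` (integer
#'   matrix), `valid_mask`, `resolution`, and the ROI bounding-box `origin`.
#' @export
build_density_map <- function(centroids, roi, resolution) {
  if (resolution <= 0) rp_abort("resolution must be positive")
  xy <- as.matrix(centroids)[, 1:2, drop = FALSE]
  if (is.matrix(roi) || is.data.frame(roi)) {
    poly <- as.matrix(roi)[, 1:2, drop = FALSE]
    bb <- c(min(poly[, 1]), min(poly[, 2]), max(poly[, 1]), max(poly[, 2]))
  } else {
    poly <- NULL
    bb <- c(0, 0, roi[1], roi[2])
  }
  if (bb[3] <= bb[1] || bb[4] <= bb[2]) rp_abort("ROI has zero extent")
  nx <- ceiling((bb[3] - bb[1]) / resolution)
  ny <- ceiling((bb[4] - bb[2]) / resolution)
  counts <- matrix(0L, nx, ny)
  if (nrow(xy) > 0) {
    ix <- floor((xy[, 1] - bb[1]) / resolution) + 1
    iy <- floor((xy[, 2] - bb[2]) / resolution) + 1
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    tab <- table(factor(ix[ok], levels = seq_len(nx)),
                 factor(iy[ok], levels = seq_len(ny)))
    counts <- matrix(as.integer(tab), nx, ny)
  }
  cx <- bb[1] + (seq_len(nx) - 0.5) * resolution
  cy <- bb[2] + (seq_len(ny) - 0.5) * resolution
  valid <- if (is.null(poly)) {
    outer(cx <= bb[3], cy <= bb[4], "&")
  } else {
    matrix(rp_point_in_polygon(rep(cx, ny), rep(cy, each = nx), poly), nx, ny)
  }
  counts[!valid] <- 0L
  structure(
    list(counts = counts, valid_mask = valid, resolution = resolution,
         origin = bb[1:2]),
    class = "rp_density_map"
  )
}

# even-odd ray casting, vectorised over query points
rp_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Texture features of a cell-density map
#'
#' Runs the 91-feature engine in 2D on the raw tile counts restricted to the
#' valid mask, with fixed-bin-count discretization (counts are low-range
#' integers).
#'
#' @param map An `rp_density_map`.
#' @param config Feature-engine configuration; default fixed bin count 32.
#' @return Named numeric vector of 91 features.
#' @export
density_map_features <- function(map, config = fe_config("count", bin_count = 32)) {
  if (!any(map$valid_mask)) rp_abort("density map has no valid tile")
  extract_features(map$counts * 1.0, map$valid_mask, config,
                   spacing = rep(map$resolution, 2))
}

#' Assemble the per-patient pathomic feature block
#'
#' Concatenates, per patient: the 65 aggregated detection measurements
#' ([aggregate_detections()]) and the 91 density-map texture features at each
#' resolution (density maps are computed per slide and the features averaged
#' across slides). 65 + 4 x 91 = 429 columns under the default resolutions.
#'
#' @param cohort An `rp_cohort`.
#' @param resolutions Density-map resolutions in micrometres.
#' @param config Feature-engine configuration for the density maps.
#' @return A tibble: `patient_id`, `n_slides`, then 429 feature columns
#'   (density-map blocks prefixed `CD50um`, `CD100um`, ...).
#' @export
pathomic_block <- function(cohort, resolutions = c(50, 100, 150, 200),
                           config = fe_config("count", bin_count = 32)) {
  rows <- purrr::map(cohort$patients, function(p) {
    if (length(p$slides) == 0) rp_abort("patient ", p$id, " has no slides")
    agg <- aggregate_detections(p$slides)
    cd <- purrr::map(resolutions, function(r) {
      per_slide <- purrr::map(p$slides, function(s) {
        if (nrow(s) == 0) return(NULL)
        m <- build_density_map(
          s[, rp_centroid_cols[2:3]], p$roi$size_um, r)
        density_map_features(m, config)
      })
      per_slide <- per_slide[!vapply(per_slide, is.null, logical(1))]
      fv <- colMeans(do.call(rbind, per_slide))
      names(fv) <- paste0("CD", r, "um_", names(fv))
      fv
    })
    dplyr::bind_cols(
      tibble::tibble(patient_id = p$id, n_slides = length(p$slides)),
      tibble::as_tibble_row(agg),
      tibble::as_tibble_row(unlist(cd))
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-patient annotation block for the preliminary cellularity analysis
#'
#' Computes [annotation_measurements()] per slide and averages across a
#' patient's slides.
#'
#' @param cohort An `rp_cohort`.
#' @return Tibble with one row per patient.
#' @export
annotation_block <- function(cohort) {
  purrr::map_dfr(cohort$patients, function(p) {
    ms <- purrr::map_dfr(p$slides, annotation_measurements,
                         roi_area = p$roi$area_um2)
    out <- dplyr::summarise(ms, dplyr::across(dplyr::everything(), mean))
    tibble::add_column(out, patient_id = p$id, .before = 1)
  })
}

#' @export
print.rp_density_map <- function(x, ...) {
  cat("<rp_density_map> ", nrow(x$counts), "x", ncol(x$counts),
      " tiles @ ", x$resolution, " um; ", sum(x$counts),
      " nuclei in ", sum(x$valid_mask), " valid tiles\n", sep = "")
  invisible(x)
}
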