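#' Synthetic cohort configuration
#'
#' Parameters of the simulated radiology + pathology cohort. Each patient
#' carries a latent tissue-state vector; its first channel is shared between
#' the two imaging scales (scaled by `coupling`), the remaining channels
#' alternate radiology-only / pathology-only so that, at `coupling = 0`, the
#' two blocks are exactly independent and every cross-scale pair is null.
#'
#' Defaults emulate the scale of a single-site glioblastoma cohort: 48
#' patients, ADC-like quantitative maps (1e-6 mm^2/s units) and T1C-like
#' images with an arbitrary per-patient affine intensity scale, 1-3 H&E
#' slides per patient with ~1200 nuclei/mm^2 over a 1 x 1 mm region of
#' interest.
#'
#' @param n_patients Number of patients (>= 3). Default 48.
#' @param n_latent Number of latent tissue channels (>= 1). Default 3.
#' @param coupling Cross-scale coupling strength in `[0, 1]`; 0 gives a null
#'   cohort. Default 0.6.
#' @param noise_sd Patient-level noise SD on every latent-driven parameter,
#'   on the same scale as the latent scores. Default 0.3.
#' @param slides_per_patient Integer range `c(min, max)` of slides. Default 1-3.
#' @param volume_shape Volume dimensions in voxels. Default `c(32, 32, 16)`.
#' @param voxel_spacing Voxel spacing in mm. Default `c(1, 1, 2)`.
#' @param roi_size_um Slide ROI width/height in micrometres. Default 1000 x 1000.
#' @param nuclei_intensity Expected nuclei per mm^2. Default 1200.
#' @param seed Master seed; per-patient substreams are derived from it by
#'   fixed offsets, so patient k is reproducible independently of cohort size.
#' @return An object of class `rp_cohort_config`.
#' @export
cohort_config <- function(n_patients = 48, n_latent = 3, coupling = 0.6,
                          noise_sd = 0.3, slides_per_patient = c(1, 3),
                          volume_shape = c(32, 32, 16),
                          voxel_spacing = c(1, 1, 2),
                          roi_size_um = c(1000, 1000),
                          nuclei_intensity = 1200, seed = 1) {
  if (n_patients < 3) rp_abort("n_patients must be >= 3")
  if (n_latent < 1) rp_abort("n_latent must be >= 1")
  if (coupling < 0 || coupling > 1) rp_abort("coupling must lie in [0, 1]")
  if (noise_sd < 0) rp_abort("noise_sd must be >= 0")
  if (any(volume_shape < 4) || length(volume_shape) != 3) {
    rp_abort("volume_shape must be three extents >= 4 voxels")
  }
  if (any(voxel_spacing <= 0)) rp_abort("voxel_spacing must be positive")
  if (any(roi_size_um <= 0)) rp_abort("roi_size_um must be positive")
  if (nuclei_intensity <= 0) rp_abort("nuclei_intensity must be positive")
  sl <- as.integer(slides_per_patient)
  if (length(sl) != 2 || sl[1] < 1 || sl[2] < sl[1]) {
    rp_abort("slides_per_patient must be an increasing integer range >= 1")
  }
  structure(
    list(n_patients = as.integer(n_patients), n_latent = as.integer(n_latent),
         coupling = coupling, noise_sd = noise_sd, slides_per_patient = sl,
         volume_shape = as.integer(volume_shape), voxel_spacing = voxel_spacing,
         roi_size_um = roi_size_um, nuclei_intensity = nuclei_intensity,
         seed = as.integer(seed)),
    class = "rp_cohort_config"
  )
}

# separable Gaussian smoothing of a 2D/3D array; truncated-kernel rows are
# renormalised so edges are not dimmed
rp_gauss_smooth <- function(a, sigma = 1.5) {
  dm <- dim(a)
  r <- ceiling(2.5 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  for (ax in seq_along(dm)) {
    n <- dm[ax]
    km <- matrix(0, n, n)
    for (d in (-r):r) {
      i <- seq_len(n)
      j <- i + d
      ok <- j >= 1 & j <= n
      km[cbind(i[ok], j[ok])] <- k[d + r + 1]
    }
    km <- km / rowSums(km)
    perm <- c(ax, setdiff(seq_along(dm), ax))
    ap <- aperm(a, perm)
    ap <- array(km %*% matrix(ap, dm[ax]), dm[perm])
    a <- aperm(ap, order(perm))
  }
  a
}

# ellipsoidal volume-of-interest mask centred in the volume
rp_voi_mask <- function(dm, frac = 0.62) {
  semi <- pmax(dm * frac / 2, 1.5)
  ctr <- (dm + 1) / 2
  ix <- array(slice.index(array(0, dm), 1), dm)
  iy <- array(slice.index(array(0, dm), 2), dm)
  iz <- array(slice.index(array(0, dm), 3), dm)
  ((ix - ctr[1]) / semi[1])^2 + ((iy - ctr[2]) / semi[2])^2 +
    ((iz - ctr[3]) / semi[3])^2 <= 1
}

# latent channel roles: 1 shared, then alternating radiology / pathology
rp_latent_roles <- function(k) {
  if (k == 1) return("shared")
  c("shared", rep(c("radiology", "pathology"), length.out = k - 1))
}

rp_planted_pairs <- function() {
  tibble::tibble(
    radiomic = rep(c("ADC_firstorder_Mean", "T1C_firstorder_Mean"), each = 6),
    pathomic = rep(c(paste0("CD", c(50, 100, 150, 200), "um_firstorder_Mean"),
                     "Haralick ASM F0", "Haralick IMOC2 F12"), 2),
    sign = rep(c(-1, -1, -1, -1, 1, -1), 2)
  )
}

# detection-mark columns carrying no latent loading at all (null-certified)
rp_null_mark_cols <- function() {
  grep("Eosin", rp_intensity_names, value = TRUE)
}

#' Generate a synthetic radiology + pathology cohort
#'
#' Simulates, per patient: an ADC-like quantitative volume and a T1C-like
#' volume (with an arbitrary per-patient affine intensity transform) inside
#' an ellipsoidal VOI; and 1-3 slides of nuclear detections drawn as an
#' inhomogeneous Poisson point pattern (thinning of a homogeneous pattern
#' under a smooth log-density field) with the full 65-column measurement
#' schema: sampled shape/intensity/Haralick marks plus Delaunay columns
#' computed from the generated centroids.
#'
#' The shared latent channel raises ADC/T1C VOI intensity while lowering
#' nuclear density and shifting two intranuclear Haralick marks, so the
#' planted cross-scale pairs recorded in the ground truth have known signs.
#' Eosin intensity columns carry no latent loading and certify null pairs.
#'
#' @param config A [cohort_config()].
#' @return An object of class `rp_cohort`: list with `patients`,
#'   `ground_truth` (`latent_scores`, `coupled_pairs`, `null_pairs`,
#'   `all_null`) and the `config` echo.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 3, nuclei_intensity = 150,
#'                                      seed = 7))
#' length(coh$patients)
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "rp_cohort_config")) rp_abort("config must come from cohort_config()")
  K <- config$n_latent
  roles <- rp_latent_roles(K)
  zmat <- matrix(NA_real_, config$n_patients, K)
  patients <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    p_seed <- config$seed + 20000L + 37L * i
    patients[[i]] <- withr::with_seed(p_seed, {
      z <- rnorm(K)
      zmat[i, ] <- z
      rp_generate_patient(sprintf("P%03d", i), z, roles, config)
    })
  }
  coupled <- if (config$coupling > 0) rp_planted_pairs() else rp_planted_pairs()[0, ]
  nulls <- tidyr::expand_grid(
    radiomic = c(rp_feature_names(prefix = "ADC"), rp_feature_names(prefix = "T1C")),
    pathomic = rp_null_mark_cols()
  )
  structure(
    list(
      patients = patients,
      ground_truth = list(latent_scores = zmat, coupled_pairs = coupled,
                          null_pairs = nulls, all_null = config$coupling == 0),
      config = config
    ),
    class = "rp_cohort"
  )
}

# one patient: two volumes + slides (called inside the patient RNG substream)
rp_generate_patient <- function(id, z, roles, config) {
  cpl <- config$coupling
  nsd <- config$noise_sd
  z_sh <- z[1]
  u_rad <- if (any(roles == "radiology")) mean(z[roles == "radiology"]) else 0
  u_path <- if (any(roles == "pathology")) mean(z[roles == "pathology"]) else 0
  dm <- config$volume_shape
  mask <- rp_voi_mask(dm)

  # --- ADC-like quantitative map (1e-6 mm^2/s) -----------------------------
  shared_adc <- cpl * z_sh + nsd * rnorm(1)
  tex <- rp_gauss_smooth(array(rnorm(prod(dm)), dm), 1.5)
  tex <- tex / sd(tex)
  adc <- array(800 + 30 * rnorm(prod(dm)), dm)
  adc[mask] <- 1100 + 150 * shared_adc +
    80 * (1 + 0.4 * tanh(u_rad)) * tex[mask] + 20 * rnorm(sum(mask))

  # --- T1C-like image, arbitrary per-patient affine intensity scale --------
  shared_t1c <- cpl * z_sh + nsd * rnorm(1)
  tex2 <- rp_gauss_smooth(array(rnorm(prod(dm)), dm), 1.5)
  tex2 <- tex2 / sd(tex2)
  t1c <- array(100 + 6 * rnorm(prod(dm)), dm)
  t1c[mask] <- 180 + 40 * shared_t1c +
    25 * (1 + 0.4 * tanh(u_rad)) * tex2[mask] + 6 * rnorm(sum(mask))
  aff_scale <- exp(runif(1, -0.7, 0.7))
  aff_shift <- runif(1, -50, 200)
  t1c <- aff_scale * t1c + aff_shift

  # --- slides --------------------------------------------------------------
  sl_rng <- config$slides_per_patient
  n_slides <- if (sl_rng[1] == sl_rng[2]) sl_rng[1] else
    sample(seq(sl_rng[1], sl_rng[2]), 1)
  # density multiplier, mean-one over the latent/noise distribution
  dens_load <- 0.5
  a <- -dens_load * (cpl * z_sh + nsd * rnorm(1))
  dens_mult <- exp(a - dens_load^2 * (cpl^2 + nsd^2) / 2)
  # per-patient mark shifts shared across slides
  mark_shift <- list(
    asm = cpl * z_sh + nsd * rnorm(1),
    imoc2 = cpl * z_sh + nsd * rnorm(1),
    odsum = cpl * z_sh + nsd * rnorm(1)
  )
  slides <- lapply(seq_len(n_slides), function(s) {
    rp_generate_slide(sprintf("%s_S%d", id, s), config, dens_mult,
                      mark_shift, u_path)
  })

  list(
    id = id,
    volumes = list(
      ADC = list(image = adc, mask = mask, spacing = config$voxel_spacing),
      T1C = list(image = t1c, mask = mask, spacing = config$voxel_spacing)
    ),
    slides = slides,
    roi = list(size_um = config$roi_size_um,
               area_um2 = prod(config$roi_size_um))
  )
}

# inhomogeneous Poisson nuclei + 65-column marks for one slide
rp_generate_slide <- function(slide_id, config, dens_mult, mark_shift, u_path) {
  w <- config$roi_size_um[1]; h <- config$roi_size_um[2]
  area_mm2 <- w * h / 1e6
  lambda0 <- config$nuclei_intensity * dens_mult   # nuclei per mm^2
  # smooth log-density clump field on a 25 um grid, slide-mean intensity kept
  gx <- max(4L, ceiling(w / 25)); gy <- max(4L, ceiling(h / 25))
  clump_amp <- 0.4 * (1 + 0.3 * tanh(u_path))
  g <- rp_gauss_smooth(matrix(rnorm(gx * gy), gx, gy), 2)
  g <- clump_amp * g / max(sd(g), 1e-12)
  g <- g - log(mean(exp(g)))
  lam_tile <- lambda0 * exp(g)                      # per-mm^2, per tile
  lam_max <- max(lam_tile)
  n_hom <- rpois(1, lam_max * area_mm2)
  if (n_hom == 0) {
    det <- rp_empty_detections(slide_id)
    return(det)
  }
  px <- runif(n_hom, 0, w); py <- runif(n_hom, 0, h)
  tx <- pmin(ceiling(px / 25), gx); ty <- pmin(ceiling(py / 25), gy)
  keep <- runif(n_hom) < lam_tile[cbind(tx, ty)] / lam_max
  px <- px[keep]; py <- py[keep]
  n <- length(px)
  if (n == 0) return(rp_empty_detections(slide_id))

  det <- tibble::tibble(Slide = rep(slide_id, n))
  det[[rp_centroid_cols[2]]] <- px
  det[[rp_centroid_cols[3]]] <- py

  # shape marks (areas um^2, lengths um)
  area <- rlnorm(n, log(40), 0.25)
  circ <- pmin(pmax(0.80 + 0.05 * u_path + 0.06 * rnorm(n), 0.2), 1)
  ecc <- pmin(pmax(0.50 - 0.10 * u_path + 0.12 * rnorm(n), 0.05), 0.95)
  r_eq <- sqrt(area / pi)
  det[["Nucleus: Area"]] <- area
  det[["Nucleus: Perimeter"]] <- 2 * pi * r_eq / sqrt(circ)
  det[["Nucleus: Circularity"]] <- circ
  det[["Nucleus: Max caliper"]] <- 2 * r_eq * (1 + ecc)
  det[["Nucleus: Min caliper"]] <- 2 * r_eq * (1 - 0.5 * ecc)
  det[["Nucleus: Eccentricity"]] <- ecc
  det[["Nucleus/Cell area ratio"]] <- runif(n, 0.25, 0.6)

  # staining-intensity marks: plausible optical-density bases; ODSum nucleus
  # columns carry the shared latent shift, Eosin columns carry none (nulls)
  base <- c(Hematoxylin = 0.8, Eosin = 0.45, ODSum = 1.3)
  comp_f <- c(Nucleus = 1, Cytoplasm = 0.55, Cell = 0.75)
  for (nm in rp_intensity_names) {
    parts <- strsplit(nm, ": | OD ")[[1]]   # compartment, stain, stat
    b <- base[parts[2]] * comp_f[parts[1]]
    shift <- if (parts[2] == "ODSum") 0.1 * b * mark_shift$odsum else 0
    mu <- b + shift + 0.05 * b * rnorm(n)
    det[[nm]] <- switch(parts[3],
      Mean = mu,
      "Std.Dev." = abs(0.15 * b + 0.03 * b * rnorm(n)),
      Min = mu - abs(0.25 * b + 0.05 * b * rnorm(n)),
      Max = mu + abs(0.25 * b + 0.05 * b * rnorm(n))
    )
  }

  # intranuclear Haralick marks on ODSum; ASM F0 and IMOC2 F12 are the
  # planted cross-scale channels
  har_base <- c(0.20, 1.5, 0.55, 2.0, 0.65, 6.0, 3.0, 1.8, 2.6, 0.9, 1.1,
                -0.35, 0.70)
  for (k in seq_along(rp_haralick_names)) {
    nm <- rp_haralick_names[k]
    b <- har_base[k]
    shift <- if (nm == "Haralick ASM F0") 0.08 * mark_shift$asm
      else if (nm == "Haralick IMOC2 F12") -0.08 * mark_shift$imoc2
      else 0.05 * abs(b) * 0.3 * u_path
    det[[nm]] <- b + shift + 0.08 * abs(b) * rnorm(n)
  }

  dl <- delaunay_features(cbind(px, py))
  for (nm in rp_delaunay_names) det[[nm]] <- dl[[nm]]
  det
}

rp_empty_detections <- function(slide_id) {
  rp_log("slide ", slide_id, " generated with 0 nuclei")
  det <- tibble::as_tibble(setNames(
    as.list(rep(list(numeric(0)), 2 + 65)),
    c(rp_centroid_cols[2:3], rp_detection_schema()$all)
  ))
  tibble::add_column(det, Slide = character(0), .before = 1)
}

#' @export
print.rp_cohort <- function(x, ...) {
  cfg <- x$config
  cat("<rp_cohort> ", length(x$patients), " patients | coupling ",
      cfg$coupling, " | noise_sd ", cfg$noise_sd, "\n", sep = "")
  cat("  volumes: ", paste(cfg$volume_shape, collapse = "x"),
      " voxels, modalities ADC + T1C\n", sep = "")
  nsl <- vapply(x$patients, function(p) length(p$slides), integer(1))
  cat("  slides/patient: ", paste(range(nsl), collapse = "-"),
      "; planted coupled pairs: ", nrow(x$ground_truth$coupled_pairs), "\n",
      sep = "")
  invisible(x)
}
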