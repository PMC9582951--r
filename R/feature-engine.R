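#' Feature-extraction configuration
#'
#' Controls gray-level discretization and matrix construction for the texture
#' engine. Quantitative maps (e.g. ADC in 1e-6 mm^2/s) are usually discretized
#' with a fixed bin width so that bins keep an absolute physical meaning;
#' count images with a small dynamic range (cell-density maps) with a fixed
#' bin count.
#'
#' @param discretization `"width"` (fixed bin width) or `"count"` (fixed
#'   number of equal-width bins over the in-mask range).
#' @param bin_width Bin width for `"width"` discretization. Default 25.
#' @param bin_count Number of bins for `"count"` discretization. Default 32.
#' @param glcm_distance Chebyshev distance for co-occurrence pairs (voxels).
#' @param classes Feature classes to compute; default all six.
#' @return An object of class `rp_fe_config`.
#' @export
fe_config <- function(discretization = c("width", "count"),
                      bin_width = 25, bin_count = 32, glcm_distance = 1L,
                      classes = rp_feature_classes) {
  discretization <- match.arg(discretization)
  if (discretization == "width" && (!is.numeric(bin_width) || bin_width <= 0)) {
    rp_abort("bin_width must be > 0")
  }
  if (discretization == "count" && (!is.numeric(bin_count) || bin_count < 2)) {
    rp_abort("bin_count must be >= 2")
  }
  if (glcm_distance < 1) rp_abort("glcm_distance must be >= 1")
  structure(
    list(discretization = discretization, bin_width = bin_width,
         bin_count = as.integer(bin_count), glcm_distance = as.integer(glcm_distance),
         classes = match.arg(classes, rp_feature_classes, several.ok = TRUE)),
    class = "rp_fe_config"
  )
}

#' Discretize an intensity image to gray levels
#'
#' Fixed-bin-width assigns level `floor((x - min) / w) + 1`; fixed-bin-count
#' splits `[min, max]` into `k` equal-width bins with the maximum assigned to
#' bin `k`. A constant image yields a single level (`ng = 1`) under either
#' scheme.
#'
#' @param image Numeric array (2D or 3D).
#' @param mask Logical array of the same dimension, or `NULL` for all voxels.
#' @param config An [fe_config()].
#' @return List with `levels` (integer array, `NA` outside the mask) and `ng`.
#' @export
fe_discretize <- function(image, mask = NULL, config = fe_config()) {
  if (is.null(mask)) mask <- array(TRUE, dim(image))
  if (!any(mask)) rp_abort("mask is empty")
  x <- image[mask]
  if (any(!is.finite(x))) rp_abort("non-finite intensities inside the mask")
  lev <- array(NA_integer_, dim(image))
  rng <- range(x)
  if (config$discretization == "width") {
    l <- as.integer(floor((x - rng[1]) / config$bin_width)) + 1L
  } else if (rng[2] == rng[1]) {
    l <- rep(1L, length(x))
  } else {
    w <- (rng[2] - rng[1]) / config$bin_count
    l <- pmin(as.integer(floor((x - rng[1]) / w)) + 1L, config$bin_count)
  }
  lev[mask] <- l
  list(levels = lev, ng = max(l))
}

# ---------------------------------------------------------------------------
# direction sets and shifted-index machinery
# ---------------------------------------------------------------------------

# Unique (half-space) offsets: 4 in 2D, 13 in 3D; scaled by `dist`.
rp_directions <- function(ndim, dist = 1L) {
  g <- as.matrix(expand.grid(rep(list(-1L:1L), ndim)))
  keep <- apply(g, 1, function(o) {
    nz <- which(o != 0)
    length(nz) > 0 && o[nz[length(nz)]] > 0  # one representative per +/- pair
  })
  g[keep, , drop = FALSE] * dist
}

# All signed neighbour offsets (8 in 2D, 26 in 3D).
rp_neighbours <- function(ndim) {
  g <- as.matrix(expand.grid(rep(list(-1L:1L), ndim)))
  g[rowSums(g != 0) > 0, , drop = FALSE]
}

# Linear from/to indices of all voxels whose neighbour at `off` is in-bounds.
rp_shift_index <- function(dm, off) {
  nd <- length(dm)
  strides <- cumprod(c(1, dm[-nd]))
  sel <- array(TRUE, dm)
  for (k in seq_len(nd)) {
    if (off[k] == 0) next
    ix <- slice.index(sel, k)
    sel <- sel & if (off[k] > 0) ix <= dm[k] - off[k] else ix >= 1 - off[k]
  }
  from <- which(sel)
  list(from = from, to = from + as.integer(sum(off * strides)))
}

# ---------------------------------------------------------------------------
# matrix builders
# ---------------------------------------------------------------------------

# Symmetric normalized co-occurrence matrix for one direction, or NULL if the
# direction yields no valid voxel pair.
rp_glcm_matrix <- function(lev, ng, off) {
  s <- rp_shift_index(dim(lev), off)
  a <- lev[s$from]; b <- lev[s$to]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  cnt <- tabulate((a[ok] - 1L) * ng + b[ok], nbins = ng * ng)
  m <- matrix(cnt, ng, ng, byrow = TRUE)
  p <- m + t(m)
  p / sum(p)
}

# Run-length matrix (ng x max run length) for one direction.
rp_glrlm_matrix <- function(lev, ng, off) {
  dm <- dim(lev)
  nd <- length(dm)
  strides <- cumprod(c(1, dm[-nd]))
  off_lin <- as.integer(sum(off * strides))
  # next_ok[i]: TRUE if voxel i has an in-bounds neighbour at +off with equal level
  s_fwd <- rp_shift_index(dm, off)
  next_ok <- array(FALSE, dm)
  eq <- !is.na(lev[s_fwd$from]) & !is.na(lev[s_fwd$to]) & lev[s_fwd$from] == lev[s_fwd$to]
  next_ok[s_fwd$from[eq]] <- TRUE
  # run starts: in-mask voxels whose -off neighbour is absent or different
  prev_ok <- array(FALSE, dm)
  prev_ok[s_fwd$to[eq]] <- TRUE
  starts <- which(!is.na(lev) & !prev_ok)
  if (length(starts) == 0) return(NULL)
  len <- rep(1L, length(starts))
  pos <- starts
  repeat {
    adv <- next_ok[pos]
    if (!any(adv)) break
    pos[adv] <- pos[adv] + off_lin
    len[adv] <- len[adv] + 1L
  }
  g <- lev[starts]
  nr_max <- max(len)
  cnt <- tabulate((g - 1L) * nr_max + len, nbins = ng * nr_max)
  matrix(cnt, ng, nr_max, byrow = TRUE)
}

# Size-zone matrix (ng x max zone size); zones are connected components of
# equal gray level under 8-/26-connectivity.
rp_glszm_matrix <- function(lev, ng) {
  dm <- dim(lev)
  inmask <- which(!is.na(lev))
  nid <- integer(length(lev))
  nid[inmask] <- seq_along(inmask)
  offs <- rp_directions(length(dm))
  efrom <- integer(0); eto <- integer(0)
  for (r in seq_len(nrow(offs))) {
    s <- rp_shift_index(dm, offs[r, ])
    a <- lev[s$from]; b <- lev[s$to]
    ok <- !is.na(a) & !is.na(b) & a == b
    efrom <- c(efrom, nid[s$from[ok]])
    eto <- c(eto, nid[s$to[ok]])
  }
  g <- igraph::graph_from_edgelist(cbind(efrom, eto), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(inmask) - igraph::vcount(g)))
  comp <- igraph::components(g)
  zone_level <- lev[inmask][match(seq_len(comp$no), comp$membership)]
  zone_size <- comp$csize
  smax <- max(zone_size)
  cnt <- tabulate((zone_level - 1L) * smax + zone_size, nbins = ng * smax)
  matrix(cnt, ng, smax, byrow = TRUE)
}

# Dependence matrix: P[g, d + 1] = number of in-mask voxels with level g and
# d equal-valued neighbours (Chebyshev distance 1, tolerance 0).
rp_gldm_matrix <- function(lev, ng) {
  dm <- dim(lev)
  dep <- array(0L, dm)
  offs <- rp_neighbours(length(dm))
  for (r in seq_len(nrow(offs))) {
    s <- rp_shift_index(dm, offs[r, ])
    a <- lev[s$from]; b <- lev[s$to]
    ok <- !is.na(a) & !is.na(b) & a == b
    idx <- s$from[ok]
    dep[idx] <- dep[idx] + 1L
  }
  inmask <- !is.na(lev)
  d <- dep[inmask]; g <- lev[inmask]
  dmax <- max(d)
  cnt <- tabulate((g - 1L) * (dmax + 1L) + d + 1L, nbins = ng * (dmax + 1L))
  matrix(cnt, ng, dmax + 1L, byrow = TRUE)
}

# NGTDM summary: for each level i, n_i (voxels with >= 1 neighbour), and
# s_i = sum over those voxels of |i - mean(in-mask neighbours)|.
rp_ngtdm_table <- function(lev, ng) {
  dm <- dim(lev)
  nbr_sum <- array(0, dm)
  nbr_n <- array(0L, dm)
  offs <- rp_neighbours(length(dm))
  for (r in seq_len(nrow(offs))) {
    s <- rp_shift_index(dm, offs[r, ])
    a <- lev[s$from]; b <- lev[s$to]
    ok <- !is.na(a) & !is.na(b)
    idx <- s$from[ok]
    nbr_sum[idx] <- nbr_sum[idx] + b[ok]
    nbr_n[idx] <- nbr_n[idx] + 1L
  }
  use <- !is.na(lev) & nbr_n > 0
  g <- lev[use]
  diffs <- abs(g - nbr_sum[use] / nbr_n[use])
  n_i <- tabulate(g, nbins = ng)
  s_i <- vapply(seq_len(ng), function(i) sum(diffs[g == i]), numeric(1))
  list(n = n_i, s = s_i, nvp = sum(use))
}

# ---------------------------------------------------------------------------
# feature formulas
# ---------------------------------------------------------------------------

rp_firstorder_features <- function(image, mask, config, spacing = NULL) {
  x <- image[mask]
  n <- length(x)
  vv <- if (is.null(spacing)) 1 else prod(spacing)
  disc <- fe_discretize(image, mask, config)
  ph <- tabulate(disc$levels[mask], nbins = disc$ng) / n
  ph <- ph[ph > 0]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  q <- unname(quantile(x, c(0.10, 0.25, 0.5, 0.75, 0.90), type = 7))
  rob <- x[x >= q[1] & x <= q[5]]
  setNames(c(
    sum(x^2),                                   # Energy
    vv * sum(x^2),                              # TotalEnergy
    -sum(ph * log2(ph)),                        # Entropy (discretized)
    min(x), q[1], q[5], max(x), m, q[3],
    q[4] - q[2],                                # InterquartileRange
    max(x) - min(x),                            # Range
    mean(abs(x - m)),                           # MeanAbsoluteDeviation
    mean(abs(rob - mean(rob))),                 # RobustMeanAbsoluteDeviation
    sqrt(mean(x^2)),                            # RootMeanSquared
    if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0,   # Skewness
    if (m2 > 0) mean((x - m)^4) / m2^2 else 0,     # Kurtosis (non-excess)
    m2,                                         # Variance (population)
    sum(ph^2)                                   # Uniformity
  ), paste("firstorder", rp_firstorder_names, sep = "_"))
}

rp_glcm_features_one <- function(p) {
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  mu <- sum(i * p)
  sigma2 <- sum((i - mu)^2 * p)
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(p[i + j == k]), numeric(1))
  k_dif <- 0:(ng - 1)
  p_dif <- vapply(k_dif, function(k) sum(p[abs(i - j) == k]), numeric(1))
  eps <- .rp_eps
  hx <- -sum(px * log2(px + eps))
  hxy <- -sum(p[p > 0] * log2(p[p > 0]))
  pxpy <- outer(px, px)
  hxy1 <- -sum(p * log2(pxpy + eps))
  hxy2 <- -sum(pxpy * log2(pxpy + eps))
  autoc <- sum(i * j * p)
  da <- sum(k_dif * p_dif)
  corr <- if (sigma2 > 0) (autoc - mu^2) / sigma2 else 1
  # P is symmetric so the marginal entropies coincide (HX = HY)
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  setNames(c(
    autoc,                                        # Autocorrelation
    mu,                                           # JointAverage
    sum((i + j - 2 * mu)^4 * p),                  # ClusterProminence
    sum((i + j - 2 * mu)^3 * p),                  # ClusterShade
    sum((i + j - 2 * mu)^2 * p),                  # ClusterTendency
    sum((i - j)^2 * p),                           # Contrast
    corr,                                         # Correlation
    da,                                           # DifferenceAverage
    -sum(p_dif * log2(p_dif + eps)),              # DifferenceEntropy
    sum((k_dif - da)^2 * p_dif),                  # DifferenceVariance
    sum(p^2),                                     # JointEnergy
    hxy,                                          # JointEntropy
    imc1, imc2,
    sum(p / (1 + (i - j)^2)),                     # Idm
    sum(p / (1 + ((i - j) / ng)^2)),              # Idmn
    sum(p / (1 + abs(i - j))),                    # Id
    sum(p / (1 + abs(i - j) / ng)),               # Idn
    sum(p[i != j] / (i[i != j] - j[i != j])^2),   # InverseVariance
    max(p),                                       # MaximumProbability
    -sum(p_sum * log2(p_sum + eps)),              # SumEntropy
    sigma2                                        # SumSquares
  ), paste("glcm", rp_glcm_names, sep = "_"))
}

rp_glcm_features <- function(lev, ng, config) {
  dirs <- rp_directions(length(dim(lev)), config$glcm_distance)
  mats <- lapply(seq_len(nrow(dirs)), function(r) rp_glcm_matrix(lev, ng, dirs[r, ]))
  mats <- mats[!vapply(mats, is.null, logical(1))]
  if (length(mats) == 0) mats <- list(matrix(1, 1, 1))  # single-voxel mask
  fs <- vapply(mats, rp_glcm_features_one,
               numeric(length(rp_glcm_names)))
  rowMeans(fs)
}

# Shared "weighted emphasis" formula block for run-length-style matrices:
# m is ng x L counts, second index s = 1..L (run length / zone size /
# dependence size).
rp_rl_features <- function(m, np) {
  ng <- nrow(m); L <- ncol(m)
  g <- matrix(seq_len(ng), ng, L)
  s <- matrix(seq_len(L), ng, L, byrow = TRUE)
  nr <- sum(m)
  pm <- m / nr
  mu_g <- sum(g * pm); mu_s <- sum(s * pm)
  eps <- .rp_eps
  list(
    se = sum(m / s^2) / nr,              # short emphasis
    le = sum(m * s^2) / nr,              # long emphasis
    gln = sum(rowSums(m)^2) / nr,
    glnn = sum(rowSums(m)^2) / nr^2,
    sn = sum(colSums(m)^2) / nr,
    snn = sum(colSums(m)^2) / nr^2,
    perc = nr / np,
    glv = sum(pm * (g - mu_g)^2),
    sv = sum(pm * (s - mu_s)^2),
    ent = -sum(pm[pm > 0] * log2(pm[pm > 0] + eps)),
    lgle = sum(m / g^2) / nr,
    hgle = sum(m * g^2) / nr,
    slgle = sum(m / (g^2 * s^2)) / nr,
    shgle = sum(m * g^2 / s^2) / nr,
    llgle = sum(m * s^2 / g^2) / nr,
    lhgle = sum(m * g^2 * s^2) / nr
  )
}

rp_glrlm_features <- function(lev, ng, config, np) {
  dirs <- rp_directions(length(dim(lev)))
  fs <- lapply(seq_len(nrow(dirs)), function(r) {
    m <- rp_glrlm_matrix(lev, ng, dirs[r, ])
    if (is.null(m)) return(NULL)
    f <- rp_rl_features(m, np)
    c(f$se, f$le, f$gln, f$glnn, f$sn, f$snn, f$perc, f$glv, f$sv, f$ent,
      f$lgle, f$hgle, f$slgle, f$shgle, f$llgle, f$lhgle)
  })
  fs <- fs[!vapply(fs, is.null, logical(1))]
  v <- rowMeans(do.call(cbind, fs))
  setNames(v, paste("glrlm", rp_glrlm_names, sep = "_"))
}

rp_glszm_features <- function(lev, ng, np) {
  m <- rp_glszm_matrix(lev, ng)
  f <- rp_rl_features(m, np)
  setNames(c(f$se, f$le, f$gln, f$glnn, f$sn, f$snn, f$perc, f$glv, f$sv,
             f$ent, f$lgle, f$hgle, f$slgle, f$shgle, f$llgle, f$lhgle),
           paste("glszm", rp_glszm_names, sep = "_"))
}

rp_gldm_features <- function(lev, ng, np) {
  m <- rp_gldm_matrix(lev, ng)
  f <- rp_rl_features(m, np)  # s = dependence size = neighbour count + 1
  setNames(c(f$se, f$le, f$gln, f$sn, f$snn, f$glv, f$sv, f$ent,
             f$lgle, f$hgle, f$slgle, f$shgle, f$llgle, f$lhgle),
           paste("gldm", rp_gldm_names, sep = "_"))
}

rp_ngtdm_features <- function(lev, ng) {
  t <- rp_ngtdm_table(lev, ng)
  nvp <- t$nvp
  out <- setNames(numeric(5), paste("ngtdm", rp_ngtdm_names, sep = "_"))
  if (nvp == 0) { out[1] <- 1e6; return(out) }
  p <- t$n / nvp
  s <- t$s
  act <- which(p > 0)
  ngp <- length(act)
  i <- act
  den_coarse <- sum(p * s)
  out["ngtdm_Coarseness"] <- if (den_coarse > 0) min(1 / den_coarse, 1e6) else 1e6
  if (ngp > 1) {
    pi_ <- p[act]
    dd <- outer(i, i, "-")
    out["ngtdm_Contrast"] <- sum(outer(pi_, pi_) * dd^2) / (ngp * (ngp - 1)) *
      sum(s) / nvp
    den_busy <- sum(abs(outer(i * pi_, i * pi_, "-")))
    out["ngtdm_Busyness"] <- if (den_busy > 0) den_coarse / den_busy else 0
    out["ngtdm_Complexity"] <- sum(abs(dd) *
      (outer(pi_ * s[act], pi_ * s[act], "+") / outer(pi_, pi_, "+"))) / nvp
    out["ngtdm_Strength"] <- if (sum(s) > 0)
      sum(outer(pi_, pi_, "+") * dd^2) / sum(s) else 0
  }
  out
}

#' Extract the full 91-value feature vector
#'
#' Applies the six feature classes to an intensity image restricted to a mask.
#' Texture matrices are built on the discretized image; co-occurrence and
#' run-length features are averaged over the unique directions (4 in 2D, 13
#' in 3D).
#'
#' @param image Numeric 2D or 3D array.
#' @param mask Logical array of identical dimension (`NULL` = all voxels).
#' @param config An [fe_config()].
#' @param spacing Physical voxel spacing (used only by TotalEnergy).
#' @return Named numeric vector; 91 values under the default configuration.
#' @export
#' @examples
#' img <- array(rep(1:4, 16), dim = c(4, 4, 4))
#' length(extract_features(img)) # 91
extract_features <- function(image, mask = NULL, config = fe_config(),
                             spacing = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(image))
  if (!is.logical(mask)) mask <- mask > 0
  if (!identical(dim(image), dim(mask))) rp_abort("image/mask dimension mismatch")
  if (!any(mask)) rp_abort("mask is empty")
  disc <- fe_discretize(image, mask, config)
  lev <- disc$levels; ng <- disc$ng
  np <- sum(mask)
  out <- c()
  for (cl in rp_feature_classes) {
    if (!cl %in% config$classes) next
    out <- c(out, switch(cl,
      firstorder = rp_firstorder_features(image, mask, config, spacing),
      glcm = rp_glcm_features(lev, ng, config),
      glrlm = rp_glrlm_features(lev, ng, config, np),
      glszm = rp_glszm_features(lev, ng, np),
      gldm = rp_gldm_features(lev, ng, np),
      ngtdm = rp_ngtdm_features(lev, ng)
    ))
  }
  out
}
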