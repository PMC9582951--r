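# Columns that identify rows rather than carry features
rp_id_cols <- c("patient_id", "n_slides", "mask_voxels", "mean_adc")

# numeric feature sub-matrix of a block tibble
rp_feature_matrix <- function(block) {
  m <- as.matrix(block[, setdiff(names(block), rp_id_cols)])
  rownames(m) <- block$patient_id
  m
}

#' Spearman correlation with t-approximation p-value
#'
#' Average ranks are used for ties; the coefficient is the Pearson
#' correlation of the ranks and the p-value comes from the t distribution
#' with `n - 2` degrees of freedom. A constant input has undefined rank
#' correlation and yields `NA` with a log message.
#'
#' @param x,y Equal-length numeric vectors, `n >= 4`.
#' @return List with `rho` and `p`.
#' @export
#' @examples
#' spearman_cor(1:5, c(2, 1, 4, 3, 5)) # rho = 0.8
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) rp_abort("x and y must have equal length")
  if (length(x) < 4) rp_abort("need n >= 4 observations")
  if (anyNA(x) || anyNA(y)) rp_abort("missing values not allowed")
  if (sd(x) == 0 || sd(y) == 0) {
    rp_log("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- cor(rank(x), rank(y))
  list(rho = rho, p = rp_spearman_p(rho, length(x)))
}

rp_spearman_p <- function(rho, n) {
  r <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values (monotone, capped at 1), as used for the q < 0.05
#' significance rule of the correlation screen.
#'
#' @param p Vector of p-values in `[0, 1]` (`NA` passed through).
#' @return Vector of q-values.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) rp_abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Bayes factor for a correlation coefficient
#'
#' Two-sided Jeffreys-style Bayes factor for the presence of a correlation:
#' the sampling density of the observed coefficient under a bivariate normal
#' model is integrated against a stretched-beta prior on the population
#' correlation (`kappa = 1`, i.e. uniform on (-1, 1)) and compared with the
#' density under the point null. Evaluated by numerical integration; the
#' hypergeometric term is summed as a series. Applied to Spearman
#' coefficients by convention (rank correlation treated on the r scale).
#'
#' @param rho Observed correlation in (-1, 1); `|rho| = 1` returns an
#'   infinite Bayes factor with a log message.
#' @param n Sample size (>= 4).
#' @param kappa Prior concentration; 1 (uniform) by default.
#' @return List with `bf` (alternative vs null) and `log10_bf`.
#' @export
#' @examples
#' correlation_bayes_factor(0.6, 48)$log10_bf # strong evidence, > 1
correlation_bayes_factor <- function(rho, n, kappa = 1) {
  if (n < 4) rp_abort("need n >= 4")
  if (is.na(rho)) return(list(bf = NA_real_, log10_bf = NA_real_))
  if (abs(rho) >= 1 - 1e-12) {
    rp_log("|rho| = 1: Bayes factor infinite")
    return(list(bf = Inf, log10_bf = Inf))
  }
  loglik <- function(p) rp_r_log_kernel(rho, p, n)
  log_prior <- function(p) stats::dbeta((p + 1) / 2, 1 / kappa, 1 / kappa,
                                        log = TRUE) - log(2)
  # shift by the maximum of the log integrand so the quadrature stays finite
  grid <- seq(-1 + 1e-6, 1 - 1e-6, length.out = 201)
  shift <- max(loglik(grid) + log_prior(grid))
  int <- integrate(function(p) exp(loglik(p) + log_prior(p) - shift), -1, 1,
                   rel.tol = 1e-10, abs.tol = 0)$value
  log_bf <- shift + log(int) - loglik(0)
  list(bf = exp(log_bf), log10_bf = log_bf / log(10))
}

# log sampling-density kernel of the observed correlation r given population
# correlation p (constant factors in r and n cancel in the Bayes factor)
rp_r_log_kernel <- function(r, p, n) {
  (n - 1) / 2 * log1p(-p^2) - (n - 3 / 2) * log1p(-p * r) +
    log(rp_hyp2f1_half(n - 1 / 2, (1 + p * r) / 2))
}

# 2F1(1/2, 1/2; c; x) by power series (0 <= x < 1), vectorised over x
rp_hyp2f1_half <- function(c, x) {
  out <- rep(1, length(x))
  term <- rep(1, length(x))
  k <- 0
  repeat {
    term <- term * (0.5 + k)^2 / ((c + k) * (k + 1)) * x
    out <- out + term
    k <- k + 1
    if (max(term) < 1e-16 * max(out) || k > 10000) break
  }
  out
}

#' Correlation strength label
#'
#' Conventional verbal bands on the absolute coefficient: very weak
#' `[0, 0.2)`, weak `[0.2, 0.4)`, moderate `[0.4, 0.6)`, strong `[0.6, 0.8)`,
#' very strong `[0.8, 1]`.
#'
#' @param rho Correlation coefficient(s), `|rho| <= 1`.
#' @return Character vector of labels (ordered factor levels preserved as
#'   plain character).
#' @export
classify_strength <- function(rho) {
  if (any(abs(rho) > 1, na.rm = TRUE)) rp_abort("|rho| must be <= 1")
  cut(abs(rho), breaks = c(0, 0.2, 0.4, 0.6, 0.8, 1 + 1e-9),
      labels = c("very weak", "weak", "moderate", "strong", "very strong"),
      right = FALSE, include.lowest = TRUE) |> as.character()
}

#' Redundancy filter on a feature block
#'
#' Removes highly collinear features before the cross-scale screen: while any
#' retained pair has `|Spearman rho| > threshold`, the pair with the largest
#' absolute correlation is examined and the member with the larger mean
#' absolute correlation against all currently retained features is removed
#' (recomputed after every removal; ties broken by feature-name order, the
#' lexicographically later name being removed). Constant features are removed
#' up front with a log message.
#'
#' @param block Feature tibble (id columns ignored), a patients x features
#'   numeric matrix, or — detected by symmetry and a unit diagonal — an
#'   already-computed correlation matrix to filter directly.
#' @param threshold Absolute-correlation threshold, default 0.9.
#' @return List of class `rp_filter_result`: `retained` (names, input order),
#'   `removed` (tibble with the feature, the triggering partner and their
#'   correlation; constants have `NA` partners), and `cor_retained`, the
#'   Spearman correlation matrix of the retained features.
#' @export
correlation_filter <- function(block, threshold = 0.9) {
  m <- if (is.matrix(block)) block else rp_feature_matrix(block)
  if (ncol(m) < 2) rp_abort("need at least 2 features")
  is_cor <- nrow(m) == ncol(m) && isSymmetric(unname(m)) &&
    all(abs(diag(m) - 1) < 1e-12)
  if (is_cor) {
    cm <- m
    if (is.null(colnames(cm))) {
      dimnames(cm) <- rep(list(sprintf("f%d", seq_len(ncol(cm)))), 2)
    }
    removed <- tibble::tibble(feature = character(), partner = character(),
                              rho = numeric())
  } else {
    const <- apply(m, 2, function(col) sd(col) == 0)
    removed <- tibble::tibble(feature = colnames(m)[const],
                              partner = NA_character_, rho = NA_real_)
    if (any(const)) {
      rp_log("dropping ", sum(const), " constant feature(s) before the filter")
      m <- m[, !const, drop = FALSE]
    }
    cm <- cor(apply(m, 2, rank))
  }
  keep <- colnames(cm)
  repeat {
    a <- abs(cm[keep, keep, drop = FALSE])
    diag(a) <- 0
    if (length(keep) < 2 || max(a) <= threshold) break
    idx <- which(a == max(a), arr.ind = TRUE)[1, ]
    f1 <- keep[idx[1]]; f2 <- keep[idx[2]]
    mac <- rowMeans(a)
    drop_f <- if (mac[f1] > mac[f2]) f1
      else if (mac[f2] > mac[f1]) f2
      else sort(c(f1, f2))[2]
    removed <- dplyr::bind_rows(removed, tibble::tibble(
      feature = drop_f, partner = setdiff(c(f1, f2), drop_f),
      rho = cm[f1, f2]))
    keep <- setdiff(keep, drop_f)
  }
  structure(
    list(retained = keep, removed = removed,
         cor_retained = cm[keep, keep, drop = FALSE],
         threshold = threshold),
    class = "rp_filter_result"
  )
}

#' Cross-correlate two feature blocks
#'
#' All pairs (feature of block A) x (feature of block B): Spearman rho,
#' t-approximation p, Benjamini-Hochberg q over all pairs of this screen
#' jointly, correlation Bayes factor and verbal strength, sorted by `|rho|`
#' descending. Blocks must contain the same patients in the same order.
#'
#' @param block_a,block_b Feature tibbles (with `patient_id`) or numeric
#'   matrices with identical row order.
#' @param alpha Significance level on q; stored as attribute and used by
#'   [filter_heatmap()] / [autoplot.rp_associations()]. Default 0.05.
#' @param compute_bf Compute Bayes factors (TRUE by default).
#' @return A tibble of class `rp_associations` with columns
#'   `radiomic_feature`, `pathomic_feature`, `rho`, `p`, `q`, `bf`,
#'   `log10_bf`, `strength`, `significant`.
#' @export
cross_correlate <- function(block_a, block_b, alpha = 0.05, compute_bf = TRUE) {
  ma <- if (is.matrix(block_a)) block_a else rp_feature_matrix(block_a)
  mb <- if (is.matrix(block_b)) block_b else rp_feature_matrix(block_b)
  if (nrow(ma) != nrow(mb)) rp_abort("blocks have different patient counts")
  if (!is.null(rownames(ma)) && !is.null(rownames(mb)) &&
      !identical(rownames(ma), rownames(mb))) {
    rp_abort("blocks contain different patients (or a different order)")
  }
  n <- nrow(ma)
  ok_a <- apply(ma, 2, sd) > 0
  ok_b <- apply(mb, 2, sd) > 0
  if (any(!ok_a) || any(!ok_b)) {
    rp_log("excluding ", sum(!ok_a) + sum(!ok_b),
           " constant feature(s) from the screen")
  }
  ma <- ma[, ok_a, drop = FALSE]; mb <- mb[, ok_b, drop = FALSE]
  if (ncol(ma) == 0 || ncol(mb) == 0) {
    rp_log("a block has no non-constant feature: empty association table")
    tab <- tibble::tibble(radiomic_feature = character(),
                          pathomic_feature = character(), rho = numeric(),
                          p = numeric(), q = numeric(), bf = numeric(),
                          log10_bf = numeric(), strength = character(),
                          significant = logical())
    attr(tab, "n") <- n
    attr(tab, "alpha") <- alpha
    class(tab) <- c("rp_associations", class(tab))
    return(tab)
  }
  rho <- cor(apply(ma, 2, rank), apply(mb, 2, rank))
  tab <- tibble::tibble(
    radiomic_feature = rep(rownames(rho), times = ncol(rho)),
    pathomic_feature = rep(colnames(rho), each = nrow(rho)),
    rho = as.vector(rho)
  )
  tab$p <- rp_spearman_p(tab$rho, n)
  tab$q <- bh_fdr(tab$p)
  if (compute_bf) {
    bfs <- purrr::map(tab$rho, correlation_bayes_factor, n = n)
    tab$bf <- purrr::map_dbl(bfs, "bf")
    tab$log10_bf <- purrr::map_dbl(bfs, "log10_bf")
  } else {
    tab$bf <- NA_real_
    tab$log10_bf <- NA_real_
  }
  tab$strength <- classify_strength(tab$rho)
  tab$significant <- tab$q < alpha
  tab <- dplyr::arrange(tab, dplyr::desc(abs(rho)))
  attr(tab, "n") <- n
  attr(tab, "alpha") <- alpha
  class(tab) <- c("rp_associations", class(tab))
  tab
}

#' Significance-filtered correlation heatmap matrix
#'
#' Drops every row and column of a correlation matrix that contains no
#' significant cell, then zeroes the surviving non-significant cells — the
#' reduced matrix used for association heatmaps.
#'
#' @param rho_matrix Numeric matrix of correlations (rows = radiomic,
#'   columns = pathomic features).
#' @param significance_mask Logical matrix of the same shape.
#' @return The reduced matrix (possibly 0 x 0, logged if empty).
#' @export
filter_heatmap <- function(rho_matrix, significance_mask) {
  if (!identical(dim(rho_matrix), dim(significance_mask))) {
    rp_abort("matrix and mask shapes differ")
  }
  keep_r <- rowSums(significance_mask) > 0
  keep_c <- colSums(significance_mask) > 0
  if (!any(keep_r)) {
    rp_log("no significant cell: heatmap matrix is empty")
    return(rho_matrix[0, 0, drop = FALSE])
  }
  out <- rho_matrix[keep_r, keep_c, drop = FALSE]
  out[!significance_mask[keep_r, keep_c, drop = FALSE]] <- 0
  out
}

# associations tibble -> rho matrix + significance mask
rp_association_matrices <- function(assoc) {
  rn <- unique(assoc$radiomic_feature)
  cn <- unique(assoc$pathomic_feature)
  rho <- matrix(NA_real_, length(rn), length(cn), dimnames = list(rn, cn))
  sig <- matrix(FALSE, length(rn), length(cn), dimnames = list(rn, cn))
  rho[cbind(assoc$radiomic_feature, assoc$pathomic_feature)] <- assoc$rho
  sig[cbind(assoc$radiomic_feature, assoc$pathomic_feature)] <-
    assoc$significant %in% TRUE
  list(rho = rho, significant = sig)
}

#' Preliminary analysis: mean ADC against basic cellularity measures
#'
#' Spearman correlation (raw p, no multiplicity adjustment) of the per-patient
#' mean ADC inside the VOI against the ROI-normalized nuclei count,
#' extracellular area, and extracellular + cytoplasm area. On diffusion MRI,
#' higher cellularity restricts water diffusion, so the nuclei-count
#' correlation is expected to be negative.
#'
#' @param radiomic_block Tibble from [extract_radiomics()] for ADC (needs
#'   `patient_id` and `mean_adc`).
#' @param annotation Tibble from [annotation_block()].
#' @return Three-row tibble: pathomic measure, rho, p, strength.
#' @export
preliminary_adc_analysis <- function(radiomic_block, annotation) {
  d <- dplyr::inner_join(
    dplyr::select(radiomic_block, "patient_id", "mean_adc"),
    annotation, by = "patient_id")
  if (nrow(d) < 4) rp_abort("need at least 4 matched patients")
  measures <- c("nuclei_count_norm", "extracellular_norm",
                "extracellular_cytoplasm_norm")
  purrr::map_dfr(measures, function(mv) {
    s <- spearman_cor(d$mean_adc, d[[mv]])
    tibble::tibble(measure = mv, rho = s$rho, p = s$p,
                   strength = classify_strength(s$rho))
  })
}

#' @export
print.rp_filter_result <- function(x, ...) {
  cat("<rp_filter_result> ", length(x$retained), " retained, ",
      nrow(x$removed), " removed (threshold ", x$threshold, ")\n", sep = "")
  invisible(x)
}
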