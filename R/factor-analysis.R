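#' Z-normalize a feature block
#'
#' Centres every feature column at 0 and scales to sample SD 1, so that no
#' feature dominates the correlation-based compression by virtue of its
#' scale. Constant columns are an error (drop them upstream, e.g. with
#' [correlation_filter()]).
#'
#' @param block Feature tibble (id columns preserved) or numeric matrix.
#' @return Same type as the input, feature columns standardized.
#' @export
znormalize <- function(block) {
  m <- if (is.matrix(block)) block else rp_feature_matrix(block)
  s <- apply(m, 2, sd)
  if (any(s == 0)) {
    rp_abort("constant column(s): ",
             paste(head(colnames(m)[s == 0], 5), collapse = ", "))
  }
  z <- scale(m)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  if (is.matrix(block)) return(z)
  out <- block
  out[, colnames(z)] <- tibble::as_tibble(z)
  out
}

#' Ridge-regularized correlation matrix with cross-validated penalty
#'
#' Shrinks the sample Spearman-free (Pearson, on standardized data)
#' correlation matrix toward the identity, `R(lambda) = (1 - lambda) R +
#' lambda I`, rescaled to unit diagonal, and picks `lambda` on a log-spaced
#' grid in `[1e-3, 1]` by 5-fold cross-validation of the held-out Gaussian
#' log-likelihood (seeded fold assignment). Guarantees a positive-definite,
#' invertible input for the factor-analytic compression even with more
#' features than patients.
#'
#' @param z Standardized data matrix (patients x features), e.g. from
#'   [znormalize()].
#' @param folds Number of CV folds, default 5.
#' @param seed Seed for the fold assignment.
#' @param grid_size Number of candidate penalties, default 25.
#' @return List of class `rp_reg_cor`: `R` (regularized correlation),
#'   `lambda`, `cv` (tibble of per-lambda mean held-out log-likelihood).
#' @export
regularized_correlation <- function(z, folds = 5, seed = 1, grid_size = 25) {
  if (!is.matrix(z)) z <- rp_feature_matrix(z)
  n <- nrow(z); p <- ncol(z)
  if (n < folds) rp_abort("need at least as many patients as folds")
  if (p < 2) rp_abort("need at least 2 features")
  # features constant inside a small training fold yield NA correlations;
  # treat them as uncorrelated there
  safe_cor <- function(x) {
    r <- suppressWarnings(cor(x))
    if (anyNA(r)) {
      r[is.na(r)] <- 0
      diag(r) <- 1
    }
    r
  }
  r_full <- safe_cor(z)
  lambdas <- exp(seq(log(1e-3), log(1), length.out = grid_size))
  fold_id <- withr::with_seed(seed, sample(rep_len(seq_len(folds), n)))
  ll <- vapply(lambdas, function(lm) {
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      r_tr <- rp_shrink(safe_cor(z[tr, , drop = FALSE]), lm)
      rp_gauss_loglik(z[!tr, , drop = FALSE], r_tr)
    }, numeric(1)))
  }, numeric(1))
  if (all(!is.finite(ll))) rp_abort("held-out likelihood non-finite for every lambda")
  lambda <- lambdas[which.max(ll)]
  structure(
    list(R = rp_shrink(r_full, lambda), lambda = lambda,
         cv = tibble::tibble(lambda = lambdas, loglik = ll)),
    class = "rp_reg_cor"
  )
}

rp_shrink <- function(r, lambda) {
  p <- ncol(r)
  out <- (1 - lambda) * r + lambda * diag(p)
  # unit-diagonal rescale (no-op when r already has unit diagonal)
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  dimnames(out) <- dimnames(r)
  out
}

# mean per-observation Gaussian log-likelihood of rows of x under N(0, R)
rp_gauss_loglik <- function(x, r) {
  ch <- tryCatch(chol(r), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  p <- ncol(x)
  logdet <- 2 * sum(log(diag(ch)))
  q <- backsolve(ch, t(x), transpose = TRUE)
  quad <- colSums(q^2)
  mean(-0.5 * (p * log(2 * pi) + logdet + quad))
}

#' Number of factors by the Guttman lower bound
#'
#' The first Guttman bound: the number of eigenvalues of the (regularized,
#' unit-diagonal) correlation matrix strictly greater than 1. Floored at 1
#' (with a log message) and capped at the Ledermann bound
#' `floor((2p + 1 - sqrt(8p + 1)) / 2)`.
#'
#' @param R Correlation matrix (or `rp_reg_cor`).
#' @return Integer factor count.
#' @export
guttman_nfactors <- function(R) {
  if (inherits(R, "rp_reg_cor")) R <- R$R
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  m <- sum(ev > 1)
  if (m < 1) {
    rp_log("Guttman bound is 0; using a single factor")
    m <- 1L
  }
  p <- ncol(R)
  led <- floor((2 * p + 1 - sqrt(8 * p + 1)) / 2)
  if (m > led && led >= 1) {
    rp_log("Guttman bound ", m, " exceeds the Ledermann bound ", led, "; capped")
    m <- led
  }
  as.integer(max(m, 1))
}

#' Maximum-likelihood factor analysis of a correlation matrix
#'
#' Minimizes the ML discrepancy `F = log|Sigma| + tr(R Sigma^-1) - log|R| - p`
#' with `Sigma = Lambda Lambda' + diag(psi)` by profiling the loadings out of
#' the uniquenesses: for fixed `psi`, the optimal loadings come from the
#' leading eigenpairs of `psi^-1/2 R psi^-1/2`, and `psi` is optimized
#' quasi-Newton with the analytic gradient. Uniquenesses are floored at 0.005
#' (Heywood guard).
#'
#' @param R Correlation matrix (or `rp_reg_cor`), unit diagonal.
#' @param m Number of factors (>= 1, at most the Ledermann bound).
#' @param n Number of observations behind `R` (metadata, used by scores/tests).
#' @param psi_floor Lower bound on uniquenesses. Default 0.005.
#' @param max_iter Iteration cap for the optimizer. Default 1000.
#' @return Object of class `rp_factor_model`: `loadings` (p x m),
#'   `uniquenesses`, `communalities`, `m`, `n`, `discrepancy`, `converged`,
#'   `feature_names`, and `lambda_penalty`/`proportion_retained` fields
#'   filled by the higher-level wrapper.
#' @export
ml_factor_analysis <- function(R, m, n = NA_integer_, psi_floor = 0.005,
                               max_iter = 1000) {
  lambda_penalty <- NA_real_
  if (inherits(R, "rp_reg_cor")) {
    lambda_penalty <- R$lambda
    R <- R$R
  }
  p <- ncol(R)
  if (m < 1) rp_abort("m must be >= 1")
  led <- floor((2 * p + 1 - sqrt(8 * p + 1)) / 2)
  if (m > led) rp_abort("m = ", m, " exceeds the Ledermann bound ", led)
  eps <- 1e-12

  profile_fn <- function(logpsi) {
    psi <- exp(logpsi)
    sc <- 1 / sqrt(psi)
    rs <- R * tcrossprod(sc)
    ev <- eigen(rs, symmetric = TRUE, only.values = TRUE)$values
    tailv <- pmax(ev[(m + 1):p], eps)
    sum(tailv - log(tailv) - 1)
  }
  profile_gr <- function(logpsi) {
    psi <- exp(logpsi)
    sc <- 1 / sqrt(psi)
    rs <- R * tcrossprod(sc)
    e <- eigen(rs, symmetric = TRUE)
    tailv <- pmax(e$values[(m + 1):p], eps)
    w <- 1 - tailv    # dF/dpsi_j = (1/psi_j) sum_i>m (1 - lambda_i) v_ij^2
    g_psi <- rowSums(e$vectors[, (m + 1):p, drop = FALSE]^2 %*% diag(w, p - m)) / psi
    g_psi * psi   # chain rule for the log parameterization
  }

  start <- log(pmax(1 / diag(solve(R)), psi_floor))
  opt <- optim(start, profile_fn, profile_gr, method = "L-BFGS-B",
               lower = log(psi_floor), upper = log(1),
               control = list(maxit = max_iter, factr = 1e4))
  psi <- exp(opt$par)
  sc <- 1 / sqrt(psi)
  e <- eigen(R * tcrossprod(sc), symmetric = TRUE)
  load <- sqrt(psi) * e$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(m)] - 1, 0)), m)
  rownames(load) <- colnames(R)
  colnames(load) <- paste0("F", seq_len(m))
  # declare convergence on the gradient norm even if the line search stopped
  # at machine precision
  grad_norm <- max(abs(profile_gr(opt$par)))
  converged <- opt$convergence == 0 || grad_norm < 1e-6
  if (!converged) {
    rp_log("factor optimization not converged (|grad| = ",
           signif(grad_norm, 3), "): ", opt$message)
  }
  comm <- rowSums(load^2)
  structure(
    list(loadings = load, uniquenesses = setNames(psi, colnames(R)),
         communalities = comm, m = as.integer(m), n = n,
         discrepancy = opt$value, converged = converged,
         feature_names = colnames(R), lambda_penalty = lambda_penalty,
         proportion_retained = mean(comm), rotated = FALSE),
    class = "rp_factor_model"
  )
}

#' Varimax rotation with deterministic sign and order conventions
#'
#' Orthogonal varimax rotation of the loading matrix (communalities are
#' preserved); each rotated column's largest-magnitude loading is made
#' positive and columns are ordered by explained variance (sum of squared
#' loadings), descending.
#'
#' @param model An `rp_factor_model`.
#' @return The rotated model.
#' @export
rotate_varimax <- function(model) {
  load <- model$loadings
  if (model$m > 1) {
    # Kaiser row normalization, guarding zero-communality rows
    h <- sqrt(rowSums(load^2))
    hs <- ifelse(h > 0, h, 1)
    rot <- varimax(load / hs, normalize = FALSE)
    load <- (load / hs) %*% rot$rotmat * hs
  }
  # sign convention
  for (k in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, k])), k] < 0) load[, k] <- -load[, k]
  }
  ord <- order(colSums(load^2), decreasing = TRUE)
  load <- load[, ord, drop = FALSE]
  colnames(load) <- paste0("F", seq_len(ncol(load)))
  model$loadings <- load
  model$rotated <- TRUE
  model
}

#' Thomson regression factor scores
#'
#' Estimates per-patient factor scores by regressing the factors on the
#' standardized observed features: `F = Z R^-1 Lambda`, with `R` the
#' regularized correlation used for the fit (invertible by construction).
#'
#' @param z Standardized data matrix (patients x features), columns matching
#'   the model's features.
#' @param R Correlation matrix used in the fit (or `rp_reg_cor`).
#' @param model An `rp_factor_model`.
#' @return Tibble: `patient_id` (from rownames, if any) and one column per
#'   factor.
#' @export
factor_scores <- function(z, R, model) {
  if (inherits(R, "rp_reg_cor")) R <- R$R
  if (!is.matrix(z)) z <- rp_feature_matrix(z)
  if (!identical(colnames(z), model$feature_names)) {
    rp_abort("columns of z do not match the model's features")
  }
  sc <- z %*% solve(R, model$loadings)
  out <- tibble::as_tibble(sc)
  tibble::add_column(out,
    patient_id = rownames(z) %||% as.character(seq_len(nrow(z))), .before = 1)
}

#' Proportion of covariation retained by a factor model
#'
#' Mean communality: the average fraction of each feature's (unit) variance
#' explained by the common factors.
#'
#' @param model An `rp_factor_model`.
#' @return Fraction in `[0, 1]`.
#' @export
proportion_retained <- function(model) {
  mean(model$communalities)
}

#' Compress a feature block to rotated factors and scores
#'
#' Convenience wrapper chaining [znormalize()], [regularized_correlation()],
#' [guttman_nfactors()], [ml_factor_analysis()], [rotate_varimax()] and
#' [factor_scores()] for one block.
#'
#' @param block Feature tibble or matrix (already redundancy-filtered).
#' @param label Block label stored on the result (e.g. `"ADC"`).
#' @param seed Seed for the CV fold assignment.
#' @param m Optional forced factor count; default Guttman bound.
#' @return List of class `rp_factor_compression`: `model`, `scores`,
#'   `reg` (the `rp_reg_cor`), `label`.
#' @export
compress_features <- function(block, label = "block", seed = 1, m = NULL) {
  z <- if (is.matrix(block)) scale(block) else rp_feature_matrix(znormalize(block))
  reg <- regularized_correlation(z, seed = seed)
  m <- m %||% guttman_nfactors(reg)
  model <- ml_factor_analysis(reg, m, n = nrow(z))
  model <- rotate_varimax(model)
  scores <- factor_scores(z, reg, model)
  structure(list(model = model, scores = scores, reg = reg, label = label),
            class = "rp_factor_compression")
}

#' Cross-correlate two factor-score sets
#'
#' All factor pairs between two blocks: Spearman rho, BH q over the pairs of
#' this screen, Bayes factors and strength labels — the factor-level
#' counterpart of [cross_correlate()].
#'
#' @param scores_a,scores_b Tibbles from [factor_scores()] (or matrices).
#' @param alpha Significance level on q.
#' @return An `rp_associations` tibble (factor names in the feature columns).
#' @export
factor_cross_correlation <- function(scores_a, scores_b, alpha = 0.05) {
  to_mat <- function(s) {
    if (is.matrix(s)) return(s)
    m <- as.matrix(s[, setdiff(names(s), "patient_id")])
    rownames(m) <- s$patient_id
    m
  }
  cross_correlate(to_mat(scores_a), to_mat(scores_b), alpha = alpha)
}

# --- broom-style methods ----------------------------------------------------

#' Tidy a factor model into a long loading table
#'
#' @param x An `rp_factor_model`.
#' @param ... Unused.
#' @return Tibble with `feature`, `factor`, `loading`, `uniqueness`.
#' @export
tidy.rp_factor_model <- function(x, ...) {
  tibble::tibble(
    feature = rep(x$feature_names, times = x$m),
    factor = rep(colnames(x$loadings), each = length(x$feature_names)),
    loading = as.vector(x$loadings),
    uniqueness = rep(unname(x$uniquenesses), times = x$m)
  )
}

#' One-row summary of a factor model
#'
#' @param x An `rp_factor_model`.
#' @param ... Unused.
#' @return One-row tibble: factor count, penalty, proportion retained,
#'   discrepancy, convergence flag, n and p.
#' @export
glance.rp_factor_model <- function(x, ...) {
  tibble::tibble(
    n_factors = x$m, lambda_penalty = x$lambda_penalty,
    proportion_retained = proportion_retained(x),
    discrepancy = x$discrepancy, converged = x$converged,
    n = x$n, p = length(x$feature_names), rotated = x$rotated
  )
}

#' @export
print.rp_factor_model <- function(x, ...) {
  cat("<rp_factor_model> ", length(x$feature_names), " features -> ",
      x$m, " factors; ", round(100 * proportion_retained(x), 1),
      "% of covariation retained", if (x$rotated) " (varimax)", "\n", sep = "")
  invisible(x)
}

#' @export
print.rp_factor_compression <- function(x, ...) {
  cat("<rp_factor_compression> block ", x$label, " | penalty ",
      signif(x$model$lambda_penalty, 3), "\n", sep = "")
  print(x$model)
  invisible(x)
}
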