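test_that("z-normalization standardizes columns and is idempotent", {
  m <- cbind(a = c(2, 4, 6), b = c(10, 0, 5))
  z <- znormalize(m)
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))      # sample SD
  expect_true(all(abs(colMeans(z)) < 1e-12))
  expect_equal(apply(z, 2, sd), c(a = 1, b = 1))
  expect_equal(znormalize(z), z, tolerance = 1e-12)
  expect_error(znormalize(cbind(a = c(1, 1, 1), b = 1:3)), "constant")
})

test_that("ridge shrinkage has the exact limits and picks a positive penalty
           when p > n", {
  set.seed(14)
  x <- scale(matrix(rnorm(40 * 5), 40, 5))
  r <- cor(x)
  expect_equal(radiopathomics:::rp_shrink(r, 1), diag(5), ignore_attr = TRUE)
  expect_equal(radiopathomics:::rp_shrink(r, 1e-12), r, tolerance = 1e-9)

  z <- scale(matrix(rnorm(30 * 100), 30, 100))
  colnames(z) <- sprintf("f%03d", 1:100)
  reg <- regularized_correlation(z, seed = 3)
  expect_gt(reg$lambda, 0)
  ev <- eigen(reg$R, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_equal(diag(reg$R), setNames(rep(1, 100), colnames(z)))
  expect_true(isSymmetric(reg$R))
  # deterministic given the seed
  expect_identical(reg$lambda, regularized_correlation(z, seed = 3)$lambda)
})

test_that("the Guttman bound counts unit-exceeding eigenvalues with floor
           and cap", {
  r <- matrix(c(1, .8, .8, 1), 2, 2)
  expect_equal(guttman_nfactors(r), 1)    # eigenvalues 1.8, 0.2
  expect_message(m0 <- guttman_nfactors(diag(4)), "single factor")
  expect_equal(m0, 1)
  # three strongly correlated blocks -> 3
  b <- matrix(.85, 4, 4); diag(b) <- 1
  r3 <- diag(12) * 0
  for (k in 0:2) r3[k * 4 + 1:4, k * 4 + 1:4] <- b
  expect_equal(guttman_nfactors(r3), 3)
})

test_that("ML factor analysis recovers a known single-factor model and
           reproduces the unit diagonal", {
  l_true <- c(0.9, 0.8, 0.7)
  r <- l_true %*% t(l_true); diag(r) <- 1
  dimnames(r) <- rep(list(c("x", "y", "z")), 2)
  fm <- ml_factor_analysis(r, 1, n = 50)
  expect_lt(max(abs(abs(fm$loadings) - l_true)), 0.01)
  expect_equal(unname(rowSums(fm$loadings^2) + fm$uniquenesses),
               rep(1, 3), tolerance = 1e-6)
  expect_equal(unname(1 - fm$uniquenesses), unname(fm$communalities),
               tolerance = 1e-6)
  expect_error(ml_factor_analysis(r, 0), "m must be")
  expect_error(ml_factor_analysis(r, 3), "Ledermann")
})

test_that("the fit agrees with an independent ML implementation", {
  set.seed(15)
  L <- matrix(0, 9, 2)
  L[1:5, 1] <- runif(5, .5, .8); L[5:9, 2] <- runif(5, .4, .7)
  x <- matrix(rnorm(300 * 2), 300, 2) %*% t(L) +
    matrix(rnorm(300 * 9), 300, 9) %*% diag(sqrt(pmax(1 - rowSums(L^2), .1)))
  r <- cor(x); dimnames(r) <- rep(list(paste0("v", 1:9)), 2)
  fm <- ml_factor_analysis(r, 2, n = 300)
  fa <- stats::factanal(covmat = r, factors = 2, rotation = "none",
                        n.obs = 300)
  expect_equal(unname(fm$uniquenesses), unname(fa$uniquenesses),
               tolerance = 1e-4)
  # loadings agree up to an orthogonal rotation: compare the implied
  # common-variance matrices
  expect_equal(tcrossprod(fm$loadings), tcrossprod(unclass(fa$loadings)),
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("varimax rotation preserves communalities and fixes sign/order", {
  set.seed(16)
  L <- matrix(rnorm(12 * 3, 0, .5), 12, 3,
              dimnames = list(paste0("v", 1:12), paste0("F", 1:3)))
  model <- structure(
    list(loadings = L, uniquenesses = setNames(runif(12, .2, .8), rownames(L)),
         communalities = rowSums(L^2), m = 3L, n = 100L,
         discrepancy = 0, converged = TRUE, feature_names = rownames(L),
         lambda_penalty = NA_real_, proportion_retained = mean(rowSums(L^2)),
         rotated = FALSE),
    class = "rp_factor_model")
  rot <- rotate_varimax(model)
  expect_equal(rowSums(rot$loadings^2), rowSums(L^2), tolerance = 1e-9)
  # Sigma unchanged by the rotation
  expect_equal(tcrossprod(rot$loadings), tcrossprod(L), tolerance = 1e-9)
  # sign convention: each column's largest-|loading| entry is positive
  for (k in 1:3) {
    expect_gt(rot$loadings[which.max(abs(rot$loadings[, k])), k], 0)
  }
  # explained variance is non-increasing across columns
  expect_false(is.unsorted(rev(colSums(rot$loadings^2))))
  # varimax criterion does not decrease
  crit <- function(l) sum(apply(l^2, 2, var))
  expect_gte(crit(rot$loadings), crit(L) - 1e-12)

  # single factor: identity up to sign
  m1 <- model; m1$loadings <- L[, 1, drop = FALSE]; m1$m <- 1L
  r1 <- rotate_varimax(m1)
  expect_equal(abs(r1$loadings), abs(L[, 1, drop = FALSE]),
               ignore_attr = TRUE)
  # exact simple structure is a fixed point up to sign/permutation
  Ls <- rbind(diag(2), matrix(0, 4, 2))
  dimnames(Ls) <- list(paste0("v", 1:6), c("F1", "F2"))
  ms <- model
  ms$loadings <- Ls; ms$m <- 2L; ms$feature_names <- rownames(Ls)
  ms$uniquenesses <- setNames(rep(.5, 6), rownames(Ls))
  rs <- rotate_varimax(ms)
  expect_equal(abs(rs$loadings), Ls, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("Thomson regression scores match the linear-algebra identity", {
  r <- matrix(.5, 3, 3); diag(r) <- 1
  dimnames(r) <- rep(list(c("a", "b", "c")), 2)
  rr <- radiopathomics:::rp_shrink(r, 0.05)
  fm <- ml_factor_analysis(rr, 1, n = 20)
  z <- matrix(c(1, -1, 0.5, 0, 2, -2, 1, 0, -1), 3, 3,
              dimnames = list(paste0("P", 1:3), c("a", "b", "c")))
  sc <- factor_scores(z, rr, fm)
  manual <- z %*% solve(rr) %*% fm$loadings
  expect_equal(as.matrix(sc[, -1]), manual, ignore_attr = TRUE)
  # zero data -> zero scores
  z0 <- z * 0
  expect_true(all(as.matrix(factor_scores(z0, rr, fm)[, -1]) == 0))
  # mismatched columns error
  z2 <- z; colnames(z2) <- c("a", "b", "d")
  expect_error(factor_scores(z2, rr, fm), "features")
})

test_that("proportion retained is the mean communality", {
  comm <- c(0.81, 0.64, 0.49, 0.81, 0.64, 0.49)
  model <- structure(list(communalities = comm), class = "rp_factor_model")
  expect_equal(proportion_retained(model), sum(comm) / 6)
  expect_equal(proportion_retained(structure(list(communalities = rep(0, 4)),
                                             class = "rp_factor_model")), 0)
  expect_equal(proportion_retained(structure(
    list(communalities = rep(0.995, 4)), class = "rp_factor_model")), 0.995)
})

test_that("tidy and glance expose the model in broom style", {
  l_true <- c(0.9, 0.8, 0.7)
  r <- l_true %*% t(l_true); diag(r) <- 1
  dimnames(r) <- rep(list(c("x", "y", "z")), 2)
  fm <- ml_factor_analysis(r, 1, n = 50)
  td <- tidy(fm)
  expect_identical(names(td), c("feature", "factor", "loading", "uniqueness"))
  expect_equal(nrow(td), 3)
  gl <- glance(fm)
  expect_equal(gl$n_factors, 1)
  expect_equal(gl$p, 3)
  expect_true(gl$converged)
})

test_that("factor scores of coupled blocks correlate while independent
           blocks stay null", {
  set.seed(17)
  n <- 120
  shared <- rnorm(n)
  a <- sapply(1:6, function(i) 0.8 * shared + rnorm(n, 0, .5))
  b <- sapply(1:6, function(i) -0.8 * shared + rnorm(n, 0, .5))
  colnames(a) <- paste0("a", 1:6); colnames(b) <- paste0("b", 1:6)
  rownames(a) <- rownames(b) <- paste0("P", 1:n)
  ca <- compress_features(a, "A", seed = 1)
  cb <- compress_features(b, "B", seed = 1)
  fa <- factor_cross_correlation(ca$scores, cb$scores)
  expect_true(any(fa$significant & abs(fa$rho) >= 0.4))

  ind <- matrix(rnorm(n * 6), n, 6, dimnames = list(rownames(a), paste0("c", 1:6)))
  ci <- compress_features(ind, "C", seed = 1)
  fi <- factor_cross_correlation(ca$scores, ci$scores)
  expect_lt(mean(fi$significant), 0.25)
})
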