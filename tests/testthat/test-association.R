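test_that("Spearman correlation matches the rank formula and is monotone
           invariant", {
  s <- spearman_cor(1:5, c(2, 1, 4, 3, 5))
  expect_equal(s$rho, 0.8)   # 1 - 6*sum(d^2)/(n(n^2-1)) with d^2 sum = 4
  expect_equal(spearman_cor(1:6, (1:6)^3)$rho, 1)        # identity ranks
  x <- c(0.3, 1.2, 2.5, 3.1, 4.8)
  expect_equal(spearman_cor(x, exp(x))$rho, 1)           # monotone invariance
  expect_message(s0 <- spearman_cor(rep(1, 5), 1:5), "constant")
  expect_true(is.na(s0$rho))
  expect_error(spearman_cor(1:3, 1:3), "n >= 4")
  # p-value equals the t approximation
  st <- spearman_cor(1:8, c(2, 1, 4, 3, 6, 5, 8, 7))
  tt <- st$rho * sqrt(6 / (1 - st$rho^2))
  expect_equal(st$p, 2 * pt(-abs(tt), 6))
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  p <- sort(runif(20))
  q <- bh_fdr(p)
  expect_true(all(diff(q) >= -1e-15))        # monotone on sorted input
  expect_true(all(q >= p))
  # oracle equivalence on random vectors: q_i = min over j >= i of m*p_j/j
  set.seed(4)
  for (rep in 1:10) {
    p <- runif(sample(3:50, 1))
    m <- length(p)
    o <- order(p)
    qs <- rev(cummin(rev(m * p[o] / seq_len(m))))
    oracle <- pmin(qs[match(seq_len(m), o)], 1)
    expect_equal(bh_fdr(p), oracle, tolerance = 1e-12)
  }
})

test_that("the correlation Bayes factor matches an independent quadrature
           oracle and behaves sensibly", {
  skip_if_not_installed("pracma")
  # oracle: same integral, independent 2F1 (Euler integral) and independent
  # Gauss-Kronrod quadrature
  o_hyp <- function(a, b, cc, x) {
    # Euler integral with t = u^2 to remove the t^(b-1) endpoint singularity
    f <- function(u) 2 * u^(2 * b - 1) * (1 - u^2)^(cc - b - 1) *
      (1 - x * u^2)^(-a)
    pracma::quadgk(f, 0, 1, tol = 1e-12) * gamma(cc) / (gamma(b) * gamma(cc - b))
  }
  o_bf <- function(r, n) {
    dens <- function(p) {
      vapply(p, function(pp) {
        (1 - pp^2)^((n - 1) / 2) * (1 - pp * r)^(-(n - 1.5)) *
          o_hyp(0.5, 0.5, n - 0.5, (1 + pp * r) / 2)
      }, numeric(1))
    }
    gl <- pracma::gaussLegendre(400, -1, 1)
    sum(gl$w * dens(gl$x) / 2) / dens(0)
  }
  for (case in list(c(0.6, 48), c(0.3, 30), c(-0.45, 60), c(0, 25))) {
    got <- correlation_bayes_factor(case[1], case[2])
    expect_equal(got$bf, o_bf(case[1], case[2]), tolerance = 1e-6,
                 label = paste("bf at rho", case[1]))
  }
  expect_gt(correlation_bayes_factor(0.6, 48)$log10_bf, 1)
  expect_lt(correlation_bayes_factor(0, 100)$bf, 1)
  # strictly increasing in |rho| at fixed n
  grid <- seq(0, 0.9, by = 0.1)
  bfs <- vapply(grid, function(r) correlation_bayes_factor(r, 40)$bf, numeric(1))
  expect_true(all(diff(bfs) > 0))
  expect_equal(correlation_bayes_factor(0.35, 40)$bf,
               correlation_bayes_factor(-0.35, 40)$bf, tolerance = 1e-9)
  expect_message(inf <- correlation_bayes_factor(1, 10), "infinite")
  expect_equal(inf$bf, Inf)
})

test_that("strength bands follow the conventional cuts", {
  expect_equal(classify_strength(0.45), "moderate")
  expect_equal(classify_strength(-0.652), "strong")
  expect_equal(classify_strength(0), "very weak")
  expect_equal(classify_strength(c(0.19, 0.2, 0.39, 0.4, 0.6, 0.8, 1)),
               c("very weak", "weak", "weak", "moderate", "strong",
                 "very strong", "very strong"))
  expect_error(classify_strength(1.2), "<= 1")
})

test_that("the redundancy filter removes the higher mean-correlation member
           and leaves no pair above threshold", {
  # worked 3-feature example on an explicit correlation matrix:
  # rho(a,b) = .95, rho(a,c) = .6, rho(b,c) = .3 -> a has the larger mean
  # absolute correlation and is removed
  cm <- matrix(c(1, .95, .6, .95, 1, .3, .6, .3, 1), 3, 3,
               dimnames = rep(list(c("a", "b", "c")), 2))
  res <- correlation_filter(cm, threshold = 0.9)
  expect_identical(res$removed$feature, "a")
  expect_identical(res$retained, c("b", "c"))

  # no-op when nothing exceeds the threshold
  set.seed(10)
  z2 <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, letters[1:4]))
  res2 <- correlation_filter(z2, 0.9)
  expect_identical(res2$retained, letters[1:4])

  # post-hoc invariant on a heavily collinear random block
  set.seed(11)
  base <- matrix(rnorm(30 * 3), 30, 3)
  noisy <- base[, rep(1:3, each = 4)] + matrix(rnorm(30 * 12, 0, 0.1), 30, 12)
  colnames(noisy) <- sprintf("f%02d", 1:12)
  res3 <- correlation_filter(noisy, 0.9)
  a <- abs(res3$cor_retained); diag(a) <- 0
  expect_lt(max(a), 0.9 + 1e-12)
  expect_setequal(c(res3$retained, res3$removed$feature), colnames(noisy))

  # constant features are dropped up front
  noisy2 <- cbind(noisy, const = 1)
  expect_message(res4 <- correlation_filter(noisy2, 0.9), "constant")
  expect_true("const" %in% res4$removed$feature)

  # agreement with caret on the worked example (independent implementation)
  skip_if_not_installed("caret")
  drop_idx <- caret::findCorrelation(cm, cutoff = 0.9, exact = TRUE)
  expect_identical(sort(colnames(cm)[drop_idx]), sort(res$removed$feature))
})

test_that("cross_correlate screens all pairs with joint FDR and is
           symmetric under block swap", {
  set.seed(13)
  n <- 24
  a <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("r", 1:4)))
  b <- cbind(a[, 1] + rnorm(n, 0, 0.2), matrix(rnorm(n * 2), n, 2))
  colnames(b) <- paste0("p", 1:3)
  tab <- cross_correlate(a, b, compute_bf = FALSE)
  expect_s3_class(tab, "rp_associations")
  expect_equal(nrow(tab), 12)
  expect_true(all(tab$q >= tab$p - 1e-15))
  expect_equal(tab$q, bh_fdr(tab$p))
  expect_false(is.unsorted(rev(abs(tab$rho))))   # sorted by |rho| desc
  # the planted r1-p1 pair tops the table
  expect_identical(tab$radiomic_feature[1], "r1")
  expect_identical(tab$pathomic_feature[1], "p1")

  swapped <- cross_correlate(b, a, compute_bf = FALSE)
  m1 <- radiopathomics:::rp_association_matrices(tab)$rho
  m2 <- radiopathomics:::rp_association_matrices(swapped)$rho
  expect_equal(m1, t(m2)[rownames(m1), colnames(m1)], tolerance = 1e-12)

  # self-correlation diagonal is exactly 1
  self <- cross_correlate(a, a, compute_bf = FALSE)
  diag_rows <- self$radiomic_feature == self$pathomic_feature
  expect_equal(self$rho[diag_rows], rep(1, sum(diag_rows)), tolerance = 1e-12)

  # patient mismatch errors
  rownames(a) <- paste0("P", 1:n)
  a2 <- a; rownames(a2) <- rev(rownames(a))
  rb <- b; rownames(rb) <- rownames(a)
  expect_error(cross_correlate(a2, rb), "different patients")
})

test_that("heatmap filtering drops all-nonsignificant rows/columns and
           zeroes survivors", {
  rho <- matrix(seq(0.1, 0.9, length.out = 9), 3, 3,
                dimnames = list(paste0("r", 1:3), paste0("p", 1:3)))
  sig <- matrix(FALSE, 3, 3, dimnames = dimnames(rho))
  # all significant: unchanged
  expect_equal(filter_heatmap(rho, !sig), rho)
  # single significant cell: 1x1 matrix holding that rho
  sig1 <- sig; sig1[1, 1] <- TRUE
  expect_equal(filter_heatmap(rho, sig1),
               rho[1, 1, drop = FALSE])
  # row with one significant of three: retained with zeros elsewhere
  sig2 <- sig; sig2[2, 2] <- TRUE; sig2[2, 3] <- FALSE; sig2[3, 3] <- TRUE
  out <- filter_heatmap(rho, sig2)
  expect_equal(dim(out), c(2, 2))
  expect_equal(out["r2", "p3"], 0)
  expect_equal(out["r2", "p2"], rho["r2", "p2"])
  # nothing significant: empty with a log
  expect_message(e <- filter_heatmap(rho, sig), "empty")
  expect_equal(dim(e), c(0, 0))
})

test_that("the preliminary ADC analysis returns the three records in order", {
  coh <- test_cohort(n = 6)
  adc <- extract_radiomics(coh, "ADC")
  ann <- annotation_block(coh)
  pre <- preliminary_adc_analysis(adc, ann)
  expect_equal(pre$measure, c("nuclei_count_norm", "extracellular_norm",
                              "extracellular_cytoplasm_norm"))
  expect_equal(nrow(pre), 3)
  # identity: feeding the count itself as mean ADC gives rho 1
  fake <- adc
  fake$mean_adc <- ann$nuclei_count_norm
  pre2 <- preliminary_adc_analysis(fake, ann)
  expect_equal(pre2$rho[1], 1)
})
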