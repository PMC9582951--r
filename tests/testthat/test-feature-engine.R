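test_that("discretization follows the fixed-width and fixed-count rules", {
  d <- fe_discretize(array(c(0, 10, 25, 26), c(4, 1)),
                     config = fe_config("width", bin_width = 25))
  expect_identical(as.integer(d$levels), c(1L, 1L, 2L, 2L))
  expect_identical(d$ng, 2L)

  d <- fe_discretize(array(0:3, c(4, 1)), config = fe_config("count", bin_count = 2))
  expect_identical(as.integer(d$levels), c(1L, 1L, 2L, 2L))

  # constant image collapses to a single level under either scheme
  for (cfg in list(fe_config("width", bin_width = 5),
                   fe_config("count", bin_count = 8))) {
    d <- fe_discretize(array(3.7, c(3, 3)), config = cfg)
    expect_identical(d$ng, 1L)
    expect_true(all(d$levels == 1L))
  }

  # mask restriction: out-of-mask voxels carry NA levels
  img <- array(1:8, c(2, 4))
  msk <- img > 4
  d <- fe_discretize(img, msk, fe_config("width", bin_width = 2))
  expect_true(all(is.na(d$levels[!msk])))
})

test_that("first-order statistics match direct summation", {
  f <- extract_features(array(1:4, c(2, 2)), config = fe_config("width", 1))
  expect_equal(unname(f["firstorder_Mean"]), 2.5)
  expect_equal(unname(f["firstorder_Range"]), 3)
  expect_equal(unname(f["firstorder_Energy"]), 30)
  expect_equal(unname(f["firstorder_Median"]), 2.5)
  expect_equal(unname(f["firstorder_Variance"]), 1.25)  # population variance
  expect_equal(unname(f["firstorder_RootMeanSquared"]), sqrt(30 / 4))

  fc <- extract_features(array(5, c(3, 3)), config = fe_config("count", 32))
  expect_equal(unname(fc["firstorder_Variance"]), 0)
  expect_equal(unname(fc["firstorder_Entropy"]), 0)
  expect_equal(unname(fc["firstorder_Uniformity"]), 1)
  expect_equal(unname(fc["firstorder_Skewness"]), 0)
})

test_that("texture hand examples reproduce", {
  # GLCM on [[1,2],[1,2]], horizontal only
  lev <- fe_discretize(matrix(c(1, 1, 2, 2), 2, 2),
                       config = fe_config("width", 1))$levels
  p <- radiopathomics:::rp_glcm_matrix(lev, 2L, c(0L, 1L))
  expect_equal(p, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  fo <- radiopathomics:::rp_glcm_features_one(p)
  expect_equal(unname(fo["glcm_Contrast"]), 1)
  expect_equal(unname(fo["glcm_JointEnergy"]), 0.5)

  # GLRLM: single run of 4 -> LRE 16; alternating -> SRE 1
  lev4 <- fe_discretize(matrix(1, 1, 4), config = fe_config("width", 1))$levels
  m <- radiopathomics:::rp_glrlm_matrix(lev4, 1L, c(0L, 1L))
  expect_equal(which(m > 0, arr.ind = TRUE)[, "col"], c(row = 4L),
               ignore_attr = TRUE)
  lre_h <- radiopathomics:::rp_rl_features(m, 4)$le  # horizontal direction
  expect_equal(lre_h, 16)
  falt <- extract_features(matrix(c(1, 2, 1, 2), 1, 4),
                           config = fe_config("width", 1))
  expect_equal(unname(falt["glrlm_ShortRunEmphasis"]), 1)

  # GLSZM: one 9-voxel zone -> LAE 81; four distinct levels -> SAE 1
  f9 <- extract_features(matrix(5, 3, 3), config = fe_config("width", 1))
  expect_equal(unname(f9["glszm_LargeAreaEmphasis"]), 81)
  f4 <- extract_features(matrix(c(1, 30, 60, 90), 2, 2),
                         config = fe_config("width", 1))
  expect_equal(unname(f4["glszm_SmallAreaEmphasis"]), 1)

  # GLDM on a constant 3x3: centre has 8 dependent neighbours
  mm <- radiopathomics:::rp_gldm_matrix(
    fe_discretize(matrix(1, 3, 3), config = fe_config("width", 1))$levels, 1L)
  expect_equal(mm[1, 9], 1)           # centre: dependence size 9 (8 + 1)
  expect_equal(sum(mm), 9)
  # single-voxel mask: only the zero-dependence bucket, zero variance
  msk1 <- matrix(FALSE, 3, 3); msk1[2, 2] <- TRUE
  f1 <- extract_features(matrix(1:9 * 1.0, 3, 3), msk1,
                         config = fe_config("width", 1))
  expect_equal(unname(f1["gldm_DependenceVariance"]), 0)

  # NGTDM degenerate conventions on a constant image
  fc <- extract_features(matrix(2, 3, 3), config = fe_config("width", 1))
  expect_equal(unname(fc["ngtdm_Contrast"]), 0)
  expect_equal(unname(fc["ngtdm_Busyness"]), 0)
  expect_equal(unname(fc["glcm_Contrast"]), 0)
  expect_equal(unname(fc["glcm_JointEnergy"]), 1)
  expect_equal(unname(fc["glcm_Correlation"]), 1)
})

test_that("the full vector has the documented structure", {
  img <- array(rnorm(4 * 4 * 3) * 50, c(4, 4, 3))
  f <- extract_features(img)
  expect_length(f, 91)
  expect_identical(names(f), rp_feature_names())
  expect_length(grep("^firstorder_", names(f)), 18)
  expect_length(grep("^glcm_", names(f)), 22)
  expect_length(grep("^glrlm_", names(f)), 16)
  expect_length(grep("^glszm_", names(f)), 16)
  expect_length(grep("^gldm_", names(f)), 14)
  expect_length(grep("^ngtdm_", names(f)), 5)
  # determinism
  expect_identical(f, extract_features(img))
  # empty mask errors
  expect_error(extract_features(img, array(FALSE, dim(img))), "empty")
})

test_that("features are translation-invariant and first-order features
           depend only on the in-mask multiset", {
  set.seed(21)
  img <- array(0, c(6, 6, 4))
  sub <- array(sample(1:4, 3 * 3 * 2, TRUE) * 1.0, c(3, 3, 2))
  msk <- array(FALSE, c(6, 6, 4))
  img[1:3, 1:3, 1:2] <- sub; msk[1:3, 1:3, 1:2] <- TRUE
  f1 <- extract_features(img, msk, fe_config("width", 1))
  img2 <- array(0, c(6, 6, 4)); msk2 <- array(FALSE, c(6, 6, 4))
  img2[3:5, 4:6, 2:3] <- sub; msk2[3:5, 4:6, 2:3] <- TRUE
  f2 <- extract_features(img2, msk2, fe_config("width", 1))
  expect_equal(f1, f2, tolerance = 1e-12)

  # permuting in-mask voxels leaves every first-order value unchanged
  perm <- sample(sum(msk))
  img3 <- img; img3[msk] <- img[msk][perm]
  f3 <- extract_features(img3, msk, fe_config("width", 1))
  fo <- grep("^firstorder_", names(f1))
  expect_equal(f1[fo], f3[fo], tolerance = 1e-12)
})

test_that("normalized co-occurrence matrices sum to one in every direction", {
  set.seed(31)
  for (rep in 1:5) {
    inst <- random_instance(sample(2:3, 1))
    disc <- fe_discretize(inst$image, inst$mask, fe_config("width", 1))
    dirs <- radiopathomics:::rp_directions(length(dim(inst$image)))
    for (r in seq_len(nrow(dirs))) {
      p <- radiopathomics:::rp_glcm_matrix(disc$levels, disc$ng, dirs[r, ])
      if (!is.null(p)) expect_equal(sum(p), 1, tolerance = 1e-12)
    }
  }
})

test_that("every texture class equals its brute-force oracle on small
           random instances", {
  set.seed(77)
  cfg <- fe_config("width", 1)
  n2 <- 12; n3 <- 6
  for (rep in seq_len(n2 + n3)) {
    inst <- random_instance(if (rep <= n2) 2 else 3)
    disc <- fe_discretize(inst$image, inst$mask, cfg)
    np <- sum(inst$mask)
    f <- extract_features(inst$image, inst$mask, cfg)
    for (cl in c("glcm", "glrlm", "glszm", "gldm", "ngtdm")) {
      o <- o_texture_features(disc$levels, disc$ng, cl, np)
      expect_equal(f[names(o)], o, tolerance = 1e-9,
                   label = paste("class", cl, "rep", rep))
    }
  }
})
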