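test_that("GLCM accumulates and normalizes pair counts correctly", {
  g <- compute_glcm(matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE), levels = 2,
                    offset = c(0, 1), symmetric = FALSE)
  expect_equal(g$P, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  g2 <- compute_glcm(matrix(c(0, 1, 0, 1), 2, 2, byrow = TRUE), levels = 2,
                     offset = c(0, 1), symmetric = FALSE)
  expect_equal(g2$P, matrix(c(0, 0, 1, 0), 2, 2)) # P(0,1) = 1
  const <- compute_glcm(matrix(1, 3, 3), levels = 4)
  expect_equal(const$P[1, 1], 1)
  expect_error(compute_glcm(matrix(1, 3, 3), roi = matrix(FALSE, 3, 3)),
               "empty")
})

test_that("GLCM scalar features match their closed forms on toys", {
  gd <- compute_glcm(matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE), levels = 2,
                     offset = c(0, 1), symmetric = FALSE)
  expect_equal(glcm_contrast(gd), 0)
  expect_equal(glcm_energy(gd), 0.5)
  expect_equal(glcm_homogeneity(gd), 1)
  expect_equal(glcm_correlation(gd), 1)
  go <- compute_glcm(matrix(c(0, 1, 0, 1), 2, 2, byrow = TRUE), levels = 2,
                     offset = c(0, 1), symmetric = FALSE)
  expect_equal(glcm_contrast(go), 1)
  expect_equal(glcm_homogeneity(go), 0.5)
  expect_error(glcm_correlation(go), "variance")
  ga <- compute_glcm(matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE), levels = 2,
                     offset = c(0, 1), symmetric = FALSE)
  expect_equal(glcm_correlation(ga), -1)
})

test_that("GLCM features agree exactly with pair-enumeration oracle", {
  set.seed(11)
  for (i in 1:10) {
    img <- matrix(sample(0:7, 256, replace = TRUE) / 7, 16, 16)
    for (off in list(c(0, 1), c(1, 0))) {
      g <- compute_glcm(img, levels = 8, offset = off, symmetric = TRUE)
      o <- oracle_glcm_features(img, 8, off, symmetric = TRUE)
      expect_equal(glcm_contrast(g), o$contrast, tolerance = 1e-12)
      expect_equal(glcm_energy(g), o$energy, tolerance = 1e-12)
      expect_equal(glcm_homogeneity(g), o$homogeneity, tolerance = 1e-12)
      if (!is.na(o$correlation))
        expect_equal(glcm_correlation(g), o$correlation, tolerance = 1e-12)
    }
  }
})

test_that("GLCM features are invariant to constant intensity shifts", {
  set.seed(12)
  img <- matrix(runif(256), 16, 16)
  g1 <- compute_glcm(img, levels = 8)
  g2 <- compute_glcm(img + 0.37, levels = 8)
  expect_equal(glcm_contrast(g1), glcm_contrast(g2))
  expect_equal(glcm_energy(g1), glcm_energy(g2))
  expect_equal(glcm_homogeneity(g1), glcm_homogeneity(g2))
})

test_that("first-order statistics follow the population formulas", {
  fo <- first_order_stats(matrix(1:4, 2, 2))
  expect_equal(fo$mean, 2.5)
  expect_equal(fo$sd, sqrt(1.25))
  expect_equal(fo$skewness, 0)
  expect_equal(fo$kurtosis, 1.64)
  expect_equal(fo$n_pixels, 4)
  sym <- matrix(c(1, 2, 2, 3), 2, 2)
  expect_equal(first_order_stats(sym)$skewness, 0)
  expect_error(first_order_stats(matrix(2, 3, 3)), "spread")
})

test_that("kurtosis of standard normal draws is near 3 (non-excess)", {
  set.seed(13)
  v <- matrix(rnorm(1e5), 500, 200)
  expect_equal(first_order_stats(v)$kurtosis, 3, tolerance = 0.1)
})

test_that("first-order stats match a one-pass moment oracle", {
  set.seed(14)
  img <- matrix(runif(400), 20, 20)
  roi <- matrix(runif(400) > 0.4, 20, 20)
  fo <- first_order_stats(img, roi)
  v <- img[roi]; n <- length(v)
  mu <- sum(v) / n; sd_ <- sqrt(sum((v - mu)^2) / n)
  expect_equal(fo$mean, mu, tolerance = 1e-10)
  expect_equal(fo$sd, sd_, tolerance = 1e-10)
  expect_equal(fo$skewness, sum(((v - mu) / sd_)^3) / n, tolerance = 1e-10)
  expect_equal(fo$kurtosis, sum(((v - mu) / sd_)^4) / n, tolerance = 1e-10)
})

test_that("global average pooling reduces each channel to its mean", {
  const <- array(0.7, c(4, 4, 3))
  expect_equal(gap_pool(const), rep(0.7, 3))
  ch <- array(c(1, 2, 3, 4), c(2, 2, 1))
  expect_equal(gap_pool(ch), 2.5)
  set.seed(15)
  x <- array(rnorm(32), c(4, 4, 2))
  xp <- x
  xp[, , 1] <- matrix(sample(x[, , 1]), 4, 4) # spatial permutation
  expect_equal(gap_pool(x)[1], gap_pool(xp)[1])
})

test_that("feature fusion is weighted concatenation with provenance names", {
  f <- fuse_features(c(a = 1, b = 2), c(x = 3), alpha = 1, beta = 0)
  expect_equal(f$values, c(1, 2, 0))
  expect_equal(f$names, c("deep.a", "deep.b", "hand.x"))
  f2 <- fuse_features(1:3, 4:6)
  expect_equal(f2$values, c(1:3, 4:6))
  f3 <- fuse_features(2, 4, alpha = 0.5, beta = 0.25)
  expect_equal(f3$values, c(1.0, 1.0))
  expect_error(fuse_features(numeric(0), 1), "empty")
  expect_error(fuse_features(1, 2, alpha = 0, beta = 0), "both zero")
  fs <- fuse_features(c(1, 2), c(3, 4), alpha = 2, beta = 1, method = "sum")
  expect_equal(fs$values, c(5, 8))
  expect_error(fuse_features(1:2, 1:3, method = "sum"), "equal-length")
})

test_that("scan-level fused features are finite, named, reproducible", {
  ds <- generate_dataset(6, 0.5, spec32(), seed = 21)
  ft <- extract_feature_table(ds, seed = 4)
  expect_equal(nrow(ft$X), 6)
  expect_true(all(is.finite(ft$X)))
  expect_true(all(grepl("^(deep|hand)\\.", colnames(ft$X))))
  ft2 <- extract_feature_table(ds, seed = 4)
  expect_identical(ft$X, ft2$X)
})
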