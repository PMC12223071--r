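test_that("erosion implements the footprint-fit set definition", {
  full <- matrix(TRUE, 7, 7)
  er <- erode(full, disk_se(1))
  expect_true(all(er[2:6, 2:6]))
  expect_false(any(er[1, ]) || any(er[7, ]) || any(er[, 1]) || any(er[, 7]))
  sq <- matrix(FALSE, 9, 9); sq[3:7, 3:7] <- TRUE
  er2 <- erode(sq, disk_se(1))
  expected <- matrix(FALSE, 9, 9); expected[4:6, 4:6] <- TRUE
  expect_identical(er2, expected)
  set.seed(1)
  for (i in 1:5) {
    X <- matrix(runif(64) > 0.5, 8, 8)
    expect_true(all(X[erode(X, disk_se(1))])) # anti-extensive
  }
})

test_that("dilation implements the footprint-hit definition", {
  empty <- matrix(FALSE, 8, 8)
  expect_identical(dilate(empty, disk_se(2)), empty)
  one <- matrix(FALSE, 9, 9); one[5, 5] <- TRUE
  di <- dilate(one, disk_se(2))
  expect_identical(di[3:7, 3:7], disk_se(2)$footprint)
  expect_equal(sum(di), sum(disk_se(2)$footprint))
  # closing is extensive (away from the image border, where the
  # finite-domain background convention truncates the dilation)
  set.seed(2)
  for (i in 1:5) {
    X <- matrix(FALSE, 8, 8)
    X[2:7, 2:7] <- matrix(runif(36) > 0.6, 6, 6)
    expect_true(all(erode(dilate(X, disk_se(1)), disk_se(1))[X]))
  }
})

test_that("erosion and dilation are dual on complements away from borders", {
  # the identity holds exactly when the foreground keeps a margin of at
  # least the footprint radius from the image border
  set.seed(3)
  for (i in 1:10) {
    X <- matrix(FALSE, 8, 8)
    X[2:7, 2:7] <- matrix(runif(36) > 0.5, 6, 6)
    se <- disk_se(1)
    lhs <- erode(X, se)[2:7, 2:7]
    rhs <- (!dilate(!X, se))[2:7, 2:7]
    expect_identical(lhs, rhs)
  }
})

test_that("skull stripping recovers the brain and rejects the skull ring", {
  s <- generate_phantom(phantom_spec(seed = 5))
  clean <- generate_phantom(phantom_spec(seed = 5, noise_sigma = 0))
  skull_ring <- clean$image > 0.9
  m <- skull_strip(s$image)
  expect_lt(sum(m & skull_ring) / sum(skull_ring), 0.05)
  expect_gt(sum(m & s$brain_mask) / sum(s$brain_mask), 0.90)
  lab <- EBImage::bwlabel(EBImage::Image(m * 1))
  expect_equal(max(lab), 1)
})

test_that("skull stripping of a blank image warns and returns empty", {
  expect_warning(m <- skull_strip(matrix(0, 16, 16)), "blank")
  expect_false(any(m))
})

test_that("anisotropic diffusion fixes constants and conserves the mean", {
  const <- matrix(0.4, 16, 16)
  expect_equal(anisotropic_diffusion(const, diffusion_params(n_iter = 10)),
               const)
  s <- generate_phantom(phantom_spec(seed = 6, noise_sigma = 0.1))
  img <- s$image
  for (i in 1:5) {
    nxt <- anisotropic_diffusion(img, diffusion_params(n_iter = 1))
    expect_equal(mean(nxt), mean(img), tolerance = 1e-6)
    img <- nxt
  }
  expect_identical(anisotropic_diffusion(s$image,
                                         diffusion_params(n_iter = 0)),
                   s$image)
})

test_that("diffusion shrinks noise variance monotonically on phantoms", {
  s <- generate_phantom(phantom_spec(seed = 8, noise_sigma = 0.1))
  img <- s$image
  vars <- numeric(20)
  for (i in 1:20) {
    img <- anisotropic_diffusion(img, diffusion_params(n_iter = 1))
    vars[i] <- stats::var(as.vector(img))
  }
  expect_true(all(diff(c(stats::var(as.vector(s$image)), vars)) < 0))
})

test_that("diffusion of n+m iterations equals n then m", {
  s <- generate_phantom(phantom_spec(seed = 9))
  p <- function(n) diffusion_params(n_iter = n)
  a <- anisotropic_diffusion(s$image, p(7))
  b <- anisotropic_diffusion(anisotropic_diffusion(s$image, p(4)), p(3))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("diffusion parameter validation enforces the stability range", {
  expect_error(diffusion_params(lam = 0.3), "lam")
  expect_error(diffusion_params(lam = 0), "lam")
  expect_error(diffusion_params(kappa = -1), "kappa")
})

test_that("min-max normalization is the exact affine map", {
  expect_equal(minmax_normalize(c(2, 4, 10)), c(0, 0.25, 1))
  x <- c(0, 0.3, 1)
  expect_equal(minmax_normalize(x, 0, 1), x)
  set.seed(4)
  v <- rnorm(50)
  out <- minmax_normalize(v, -2, 3)
  expect_equal(range(out), c(-2, 3))
  expect_identical(order(out), order(v))
  expect_error(minmax_normalize(rep(1, 5)), "constant")
  expect_equal(minmax_normalize(rep(1, 5), const_fill = 0.5), rep(0.5, 5))
})

test_that("mutual information matches its entropy identities", {
  s <- generate_phantom(phantom_spec(seed = 10))
  x <- s$image
  ent <- function(q, bins) {
    p <- tabulate(q, bins) / length(q)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  q <- phantomfed:::quantize_minmax(x, 32)
  expect_equal(mutual_information(x, x, 32), ent(q, 32), tolerance = 1e-10)
  # deterministic monotone relabeling preserves MI at matched binning
  expect_equal(mutual_information(x, 1 - x, 32), ent(q, 32),
               tolerance = 1e-10)
  set.seed(5)
  a <- matrix(runif(64 * 64), 64, 64)
  b <- matrix(runif(64 * 64), 64, 64)
  expect_lt(mutual_information(a, b, 16), 0.05)
  expect_gte(mutual_information(a, b, 16), 0)
  expect_error(mutual_information(a, b[1:10, 1:10]), "shape")
})

test_that("rigid registration recovers identity and known shifts", {
  s <- generate_phantom(phantom_spec(seed = 11))
  fx <- s$image
  r0 <- register_rigid(fx, fx, max_shift = 4, max_angle = 3)
  expect_lt(abs(r0$transform$dy), 0.5)
  expect_lt(abs(r0$transform$dx), 0.5)
  expect_lt(abs(r0$transform$theta), 0.5)
  mv <- matrix(0.05, 64, 64)
  mv[6:64, 1:61] <- fx[1:59, 4:64] # content moved by (+5, -3)
  r <- register_rigid(mv, fx, max_shift = 8, max_angle = 0)
  expect_lt(abs(r$transform$dy - 5), 1)
  expect_lt(abs(r$transform$dx + 3), 1)
  # attained score never below the identity-transform score
  expect_gte(r$mi, mutual_information(mv, fx, 32))
})

test_that("registration works across the pseudo-modality gap", {
  s <- generate_phantom(phantom_spec(seed = 12))
  fx <- s$image
  mv <- matrix(0.05, 64, 64)
  mv[6:64, 1:61] <- fx[1:59, 4:64]
  pm <- make_pseudo_modality(
    phantomfed:::new_labeled_scan(mv, s$brain_mask, s$tumor_mask,
                                  s$label, s$tumor_type))
  r <- register_rigid(pm$image, fx, max_shift = 8, max_angle = 0)
  expect_lt(abs(r$transform$dy - 5), 1)
  expect_lt(abs(r$transform$dx + 3), 1)
})

test_that("quality gate computes SSIM/PSNR and applies both thresholds", {
  s <- generate_phantom(phantom_spec(seed = 13))
  g <- quality_gate(s$image, s$image)
  expect_equal(g$ssim, 1, tolerance = 1e-9)
  expect_true(is.infinite(g$psnr))
  expect_true(g$accept)
  set.seed(6)
  noisy <- s$image + matrix(rnorm(4096, 0, 0.1), 64, 64)
  expect_equal(psnr(noisy, s$image), 20 * log10(1 / 0.1), tolerance = 0.5)
  blurred <- gaussian_blur(s$image, 2)
  expect_false(quality_gate(blurred, s$image, ssim_min = 0.99,
                            psnr_min = 60)$accept)
  expect_error(quality_gate(s$image, matrix(0.5, 64, 64)), "dynamic range")
})
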