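test_that("squashing keeps direction, bounds norms below one", {
  expect_equal(squash(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(sqrt(sum(squash(c(1, 0))^2)), 0.5)
  expect_gte(sqrt(sum(squash(c(1000, 0))^2)), 0.999998)
  set.seed(1)
  norms <- sapply(seq(0.1, 50, length.out = 40), function(r) {
    v <- rnorm(4); v <- v / sqrt(sum(v^2)) * r
    sqrt(sum(squash(v)^2))
  })
  expect_true(all(diff(norms) > 0)) # strictly increasing in |s|
  expect_true(all(norms < 1))
  s <- c(3, -4)
  expect_equal(squash(s) / sqrt(sum(squash(s)^2)), s / 5, tolerance = 1e-12)
  expect_error(squash(c(1, NA)), "finite")
})

test_that("routing couplings form distributions and reward agreement", {
  # single parent: softmax over one item is identically 1
  u1 <- array(rnorm(6), c(3, 2, 1))
  r1 <- dynamic_routing(u1, iters = 3)
  expect_equal(as.vector(r1$c), rep(1, 3))
  # zero predictions give zero outputs
  r0 <- dynamic_routing(array(0, c(3, 2, 2)), iters = 2)
  expect_equal(r0$v, matrix(0, 2, 2))
  # couplings are a probability distribution over parents at every depth
  set.seed(2)
  u <- array(rnorm(24), c(4, 3, 2))
  for (it in 1:3)
    expect_equal(rowSums(dynamic_routing(u, it)$c), rep(1, 4))
  # children aligned with parent 1 route there increasingly
  ua <- array(0, c(2, 2, 2))
  ua[, , 1] <- matrix(c(1, 1, 0, 0), 2, 2) # strong consistent parent-1 votes
  ua[, , 2] <- matrix(c(0.1, -0.1, 0.1, -0.1), 2, 2)
  c1 <- dynamic_routing(ua, 1)$c[, 1]
  c3 <- dynamic_routing(ua, 3)$c[, 1]
  expect_true(all(c3 > c1))
  expect_error(dynamic_routing(ua, 0), "iters")
})

test_that("classifier construction is deterministic with bounded norms", {
  cfg <- classifier_config(input_dim = 6, seed = 9)
  m1 <- build_classifier(cfg)
  m2 <- build_classifier(cfg)
  expect_identical(phantomfed:::flatten_params(m1$layers)$values,
                   phantomfed:::flatten_params(m2$layers)$values)
  set.seed(3)
  X <- matrix(rnorm(5 * 6), 5, 6)
  p1 <- predict_capsule(m1, X)
  p2 <- predict_capsule(m2, X)
  expect_identical(p1$label, p2$label)
  expect_true(all(p1$confidence >= 0 & p1$confidence < 1))
})

test_that("margin-loss gradients through squash match finite differences", {
  cfg <- classifier_config(input_dim = 3, n_primary = 2, primary_dim = 3,
                           digit_dim = 3, routing_iters = 1, seed = 11)
  model <- build_classifier(cfg)
  set.seed(4)
  X <- matrix(rnorm(4 * 3), 4, 3)
  yidx <- c(1, 2, 1, 2)
  fp <- phantomfed:::flatten_params(model$layers)
  lossfun <- function(vals) {
    m <- model
    m$layers <- phantomfed:::unflatten_params(m$layers, vals)
    fw <- phantomfed:::caps_forward(m, X)
    phantomfed:::margin_loss(fw$norms, yidx)$loss
  }
  fw <- phantomfed:::caps_forward(model, X)
  ml <- phantomfed:::margin_loss(fw$norms, yidx)
  ga <- phantomfed:::flatten_params(
    phantomfed:::caps_backward(model, fw$cache, ml$dnorm))$values
  eps <- 1e-6
  gn <- sapply(seq_along(fp$values), function(i) {
    v1 <- fp$values; v1[i] <- v1[i] + eps
    v2 <- fp$values; v2[i] <- v2[i] - eps
    (lossfun(v1) - lossfun(v2)) / (2 * eps)
  })
  relerr <- abs(gn - ga) / pmax(1e-4, abs(gn) + abs(ga))
  expect_lt(max(relerr), 1e-4)
})

test_that("zero-epoch training returns the initialization", {
  set.seed(5)
  X <- matrix(rnorm(10 * 4), 10, 4)
  y <- rep(c("a", "b"), 5)
  cfg <- classifier_config(input_dim = 4)
  fit <- train_classifier(X, y, cfg, epochs = 0, seed = 6)
  cfg$seed <- derive_seed(6, "init")
  ref <- build_classifier(cfg)
  expect_identical(fit$params,
                   phantomfed:::flatten_params(ref$layers)$values)
  expect_error(train_classifier(X, rep("a", 10), cfg), "classes")
})

test_that("a tiny capsule model overfits eight samples", {
  set.seed(7)
  X <- matrix(rnorm(8 * 6), 8, 6)
  X[5:8, ] <- X[5:8, ] + 1.5
  y <- rep(c("neg", "pos"), each = 4)
  cfg <- classifier_config(input_dim = 6)
  fit <- train_classifier(X, y, cfg, epochs = 100, lr = 1e-2,
                          batch_size = 8, seed = 8)
  expect_equal(utils::tail(fit$history$accuracy, 1), 1)
  expect_lt(utils::tail(fit$history$loss, 1),
            fit$history$loss[1]) # decreasing trend
  expect_true(all(is.finite(fit$history$loss)))
})

test_that("image-mode classifier runs forward and trains a step", {
  ds <- generate_dataset(8, 0.5, spec32(), seed = 41)
  imgs <- lapply(ds, `[[`, "image")
  y <- vapply(ds, `[[`, "", "label")
  cfg <- classifier_config(mode = "image", input_size = 32, seed = 12)
  fit <- train_classifier(imgs, y, cfg, epochs = 1, batch_size = 4,
                          seed = 13)
  pr <- predict_capsule(fit$model, imgs)
  expect_length(pr$label, 8)
  expect_true(all(pr$confidence >= 0 & pr$confidence < 1))
})

test_that("deep feature extractor yields deterministic pooled features", {
  ex <- deep_feature_extractor(input_size = 32, seed = 3)
  s <- generate_phantom(spec32(seed = 42))
  f1 <- ex(s$image)
  f2 <- deep_feature_extractor(input_size = 32, seed = 3)(s$image)
  expect_identical(f1, f2)
  expect_true(all(grepl("^gap", names(f1))))
})
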