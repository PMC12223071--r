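upd <- function(w, n, id = "c") list(weights = w, n_k = n, client_id = id,
                                     metadata = list())

test_that("fedavg is the exact sample-weighted mean", {
  u <- upd(c(1, 2, 3), 4)
  expect_equal(fedavg(list(u)), c(1, 2, 3))
  m <- fedavg(list(upd(c(0, 2), 3), upd(c(4, 6), 3)))
  expect_equal(m, c(2, 4))
  expect_equal(fedavg(list(upd(1.0, 1), upd(5.0, 3))), 4.0)
  expect_error(fedavg(list()), "empty")
  expect_error(fedavg(list(upd(1:2, 1), upd(1:3, 1))), "mismatch")
})

test_that("fedavg is linear and order-invariant to float tolerance", {
  set.seed(1)
  us <- lapply(1:7, function(i) upd(rnorm(50), sample(1:20, 1)))
  a <- fedavg(us)
  expect_equal(fedavg(lapply(us, function(u) {
    u$weights <- 3 * u$weights
    u
  })), 3 * a, tolerance = 1e-12)
  for (i in 1:5) {
    perm <- sample(us)
    expect_equal(fedavg(perm), a, tolerance = 1e-9)
  }
})

test_that("the aggregator interface admits only client updates", {
  # raw-data isolation: fedavg's surface accepts the update list and nothing
  # else - no dataset can cross this boundary
  expect_named(formals(fedavg), "updates")
})

test_that("local training starts from the broadcast weights", {
  set.seed(2)
  X <- matrix(rnorm(12 * 4), 12, 4)
  y <- rep(c("a", "b"), 6)
  cfg <- classifier_config(input_dim = 4)
  gw <- phantomfed:::flatten_params(
    build_classifier(cfg)$layers)$values
  cd <- list(X = X, y = y, client_id = "c1")
  u0 <- local_train(cd, gw, cfg, local_epochs = 0, seed = 3,
                    classes = c("a", "b"))
  expect_identical(u0$weights, gw)
  expect_equal(u0$n_k, 12L)
  u1 <- local_train(cd, gw, cfg, local_epochs = 2, seed = 3,
                    classes = c("a", "b"))
  u2 <- local_train(cd, gw, cfg, local_epochs = 2, seed = 3,
                    classes = c("a", "b"))
  expect_identical(u1$weights, u2$weights)
  expect_false(identical(u1$weights, gw))
})

test_that("failure injection drops and poisons at the configured rates", {
  us <- lapply(1:6, function(i) upd(rnorm(10), 5, paste0("c", i)))
  clean <- inject_failures(us, 0, 0, seed = 4)
  expect_identical(clean$updates, us)
  none <- inject_failures(us, 1, 0, seed = 4)
  expect_length(none$updates, 0)
  expect_true(all(none$log$dropped))
  # law of large numbers on the dropout Bernoulli
  many <- lapply(1:10000, function(i) upd(0, 1, paste0("c", i)))
  inj <- inject_failures(many, 0.10, 0, seed = 5)
  expect_lt(abs(mean(inj$log$dropped) - 0.10), 0.01)
  # poisoning perturbs surviving weights
  pois <- inject_failures(us, 0, 1, noise_sigma = 0.5, seed = 6)
  expect_true(all(pois$log$poisoned))
  expect_false(identical(pois$updates[[1]]$weights, us[[1]]$weights))
  expect_error(inject_failures(us, 1.5, 0), "rates")
})

test_that("differential privacy clips then adds calibrated noise", {
  u <- upd(rnorm(10000, 0, 0.01), 3)
  keep <- dp_noise(u, epsilon = Inf, delta = 1e-5, clip_norm = 100, seed = 7)
  expect_identical(keep$weights, u$weights) # pre-clipped, noiseless mode
  expect_true(keep$metadata$dp)
  big <- upd(rnorm(100, 0, 10), 3)
  clipped <- dp_noise(big, epsilon = Inf, delta = 1e-5, clip_norm = 1,
                      seed = 7)
  expect_lte(sqrt(sum(clipped$weights^2)), 1 + 1e-12)
  noised <- dp_noise(u, epsilon = 1, delta = 1e-5, clip_norm = 1, seed = 8)
  sigma <- 1 * sqrt(2 * log(1.25 / 1e-5)) / 1
  expect_equal(stats::sd(noised$weights - dp_noise(u, Inf, 1e-5, 1,
                                                   seed = 8)$weights),
               sigma, tolerance = 0.05 * sigma)
  expect_error(dp_noise(u, epsilon = 0), "epsilon")
  expect_error(dp_noise(u, clip_norm = 0), "clip_norm")
})

test_that("the round loop is deterministic and ledger-consistent", {
  set.seed(9)
  mk <- function(id, shift) {
    X <- matrix(rnorm(20 * 4), 20, 4)
    X[11:20, ] <- X[11:20, ] + shift
    list(X = X, y = rep(c("neg", "pos"), each = 10), client_id = id)
  }
  clients <- list(mk("c1", 2), mk("c2", 2))
  cfg <- classifier_config(input_dim = 4)
  flc <- fl_config(K = 2, rounds = 3, local_epochs = 1, dropout_rate = 0,
                   noise_rate = 0, seed = 11)
  ev <- mk("ev", 2)
  r1 <- run_simulation(flc, clients, cfg, ev)
  r2 <- run_simulation(flc, clients, cfg, ev)
  expect_identical(sapply(r1$history, `[[`, "digest"),
                   sapply(r2$history, `[[`, "digest"))
  expect_true(verify_chain(r1$ledger)$valid)
  expect_length(r1$ledger$chain, 3)
  # logged digest audits against the final weights
  expect_true(audit_round(r1$ledger, 3, r1$weights))
  # all-dropout rounds retain the previous global
  flc2 <- fl_config(K = 2, rounds = 1, local_epochs = 1, dropout_rate = 1,
                    noise_rate = 0, seed = 12)
  expect_warning(r3 <- run_simulation(flc2, clients, cfg, ev), "dropped")
  expect_true(all(vapply(r3$history, `[[`, TRUE, "skipped")))
  expect_length(r3$ledger$chain, 0)
})
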