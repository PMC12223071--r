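# Single-process federated averaging simulation: local capsule-classifier
# training per client, sample-count-weighted aggregation, client dropout and
# model-poisoning injection, optional Gaussian-mechanism differential
# privacy, and a hash-chained ledger entry per round.

#' Federated simulation configuration
#'
#' Defaults mirror a five-hospital cohort: 5 clients, 3 local epochs,
#' 10% dropout and 10% poisoning rates.
#'
#' @param K Number of clients.
#' @param rounds Communication rounds.
#' @param local_epochs Local training epochs per round.
#' @param dropout_rate Per-round probability that a client's update is lost.
#' @param noise_rate Per-round probability that a surviving client's update
#'   is poisoned with additive Gaussian noise.
#' @param noise_sigma Poisoning noise scale as a multiple of the update's
#'   root-mean-square weight.
#' @param lr Local Adam learning rate.
#' @param batch_size Local minibatch size.
#' @param dp List: `enabled`, `epsilon`, `delta`, `clip_norm` for
#'   client-level differential privacy (Gaussian mechanism).
#' @param seed Master seed.
#' @return An `fl_config`.
#' @export
fl_config <- function(K = 5, rounds = 100, local_epochs = 3,
                      dropout_rate = 0.10, noise_rate = 0.10,
                      noise_sigma = 0.5, lr = 1e-3, batch_size = 16,
                      dp = list(enabled = FALSE, epsilon = 1.0, delta = 1e-5,
                                clip_norm = 10),
                      seed = 1L) {
  for (r in c(dropout_rate, noise_rate))
    if (r < 0 || r > 1) stop("rates must be in [0, 1]")
  if (isTRUE(dp$enabled) && is.finite(dp$epsilon) && dp$epsilon <= 0)
    stop("epsilon must be > 0 when DP is enabled")
  structure(list(K = as.integer(K), rounds = as.integer(rounds),
                 local_epochs = as.integer(local_epochs),
                 dropout_rate = dropout_rate, noise_rate = noise_rate,
                 noise_sigma = noise_sigma, lr = lr,
                 batch_size = as.integer(batch_size), dp = dp,
                 seed = as.integer(seed)),
            class = "fl_config")
}

new_client_update <- function(client_id, round, n_k, weights,
                              metadata = list()) {
  if (n_k < 1) stop("n_k must be >= 1")
  structure(list(client_id = client_id, round = round, n_k = as.integer(n_k),
                 weights = weights, metadata = metadata),
            class = "client_update")
}

# pairwise (cascade) summation of a list of equal-length vectors
pairwise_sum <- function(vs) {
  while (length(vs) > 1) {
    nxt <- list()
    i <- 1
    while (i <= length(vs)) {
      nxt[[length(nxt) + 1]] <-
        if (i + 1 <= length(vs)) vs[[i]] + vs[[i + 1]] else vs[[i]]
      i <- i + 2
    }
    vs <- nxt
  }
  vs[[1]]
}

#' Federated averaging
#'
#' `w = sum_k (n_k / N) w_k` with `N = sum_k n_k`: the sample-count-weighted
#' mean of client weight vectors, accumulated with pairwise summation so the
#' result is order-stable to float tolerance.
#'
#' @param updates List of client updates (each with `weights`, `n_k`).
#' @return Aggregated flat weight vector.
#' @export
#' @examples
#' u1 <- list(weights = 1.0, n_k = 1)
#' u2 <- list(weights = 5.0, n_k = 3)
#' fedavg(list(u1, u2)) # 4
fedavg <- function(updates) {
  if (length(updates) == 0) stop("empty update list")
  len <- length(updates[[1]]$weights)
  for (u in updates)
    if (length(u$weights) != len) stop("weight length mismatch")
  N <- sum(vapply(updates, function(u) as.numeric(u$n_k), numeric(1)))
  pairwise_sum(lapply(updates, function(u) (u$n_k / N) * u$weights))
}

#' Local training step for one client
#'
#' Continues capsule-classifier training from the broadcast global weights
#' on the client's local data only; returns a `client_update` carrying the
#' new weights and the local sample count — raw data never crosses this
#' boundary.
#'
#' @param client_data List with `X` (feature matrix) and `y` (labels).
#' @param global_weights Flat global parameter vector.
#' @param clf_config A [classifier_config()].
#' @param local_epochs Local epochs (0 returns the global weights).
#' @param lr,batch_size Local optimizer settings.
#' @param seed Seed for this client/round.
#' @param classes Fixed global class ordering.
#' @return A `client_update`.
#' @export
local_train <- function(client_data, global_weights, clf_config,
                        local_epochs = 3, lr = 1e-3, batch_size = 16,
                        seed = 1L, classes = NULL) {
  n_k <- nrow(client_data$X)
  if (is.null(n_k) || n_k == 0) stop("empty client dataset")
  fit <- train_classifier(client_data$X, client_data$y, clf_config,
                          epochs = local_epochs, lr = lr,
                          batch_size = batch_size, seed = seed,
                          init_params = global_weights, classes = classes,
                          allow_single_class = TRUE)
  loss <- if (nrow(fit$history)) utils::tail(fit$history$loss, 1) else NA_real_
  new_client_update(client_data$client_id %||% "client", NA_integer_, n_k,
                    fit$params,
                    metadata = list(local_epochs = local_epochs, loss = loss))
}

#' Inject communication failures and model poisoning
#'
#' Each client is independently dropped with `dropout_rate`; each survivor
#' is independently poisoned with additive Gaussian noise of standard
#' deviation `noise_sigma` times the update's RMS weight.
#'
#' @param updates List of `client_update`s.
#' @param dropout_rate,noise_rate Probabilities in `[0, 1]`.
#' @param noise_sigma Poisoning scale (multiple of weight RMS).
#' @param seed Seed.
#' @return List: `updates` (survivors, possibly perturbed), `log`
#'   (data frame: client_id, dropped, poisoned).
#' @export
inject_failures <- function(updates, dropout_rate = 0.1, noise_rate = 0.1,
                            noise_sigma = 0.5, seed = 1L) {
  if (dropout_rate < 0 || dropout_rate > 1 || noise_rate < 0 || noise_rate > 1)
    stop("rates must be in [0, 1]")
  with_seed(seed, {
    dropped <- stats::runif(length(updates)) < dropout_rate
    poisoned <- !dropped & stats::runif(length(updates)) < noise_rate
    out <- list()
    for (i in seq_along(updates)) {
      if (dropped[i]) next
      u <- updates[[i]]
      if (poisoned[i]) {
        rms <- sqrt(mean(u$weights^2))
        u$weights <- u$weights +
          stats::rnorm(length(u$weights), 0, noise_sigma * rms)
        u$metadata$poisoned <- TRUE
      }
      out[[length(out) + 1]] <- u
    }
    list(updates = out,
         log = data.frame(
           client_id = vapply(updates, `[[`, "", "client_id"),
           dropped = dropped, poisoned = poisoned))
  })
}

#' Client-level differential privacy (Gaussian mechanism)
#'
#' Clips the update to L2 norm `clip_norm`, then adds per-coordinate
#' Gaussian noise with `sigma = clip_norm * sqrt(2 ln(1.25/delta)) / epsilon`.
#' `epsilon = Inf` is the noiseless mode (clip only).
#'
#' @param update A `client_update`.
#' @param epsilon,delta Privacy budget.
#' @param clip_norm Positive clipping bound.
#' @param seed Seed.
#' @return The privatized `client_update` (metadata flag `dp = TRUE`).
#' @export
dp_noise <- function(update, epsilon = 1.0, delta = 1e-5, clip_norm = 1,
                     seed = 1L) {
  if (clip_norm <= 0) stop("clip_norm must be > 0")
  if (epsilon <= 0) stop("epsilon must be > 0")
  w <- update$weights
  nrm <- sqrt(sum(w^2))
  if (nrm > clip_norm) w <- w * (clip_norm / nrm)
  if (is.finite(epsilon)) {
    sigma <- clip_norm * sqrt(2 * log(1.25 / delta)) / epsilon
    w <- w + with_seed(seed, stats::rnorm(length(w), 0, sigma))
  }
  update$weights <- w
  update$metadata$dp <- TRUE
  update
}

#' Run the federated simulation
#'
#' Per round: broadcast the global weights, train each client locally,
#' inject dropout/poisoning, optionally apply differential-privacy noise,
#' aggregate with [fedavg()], append the global-model digest to the ledger,
#' and evaluate on the held-out set. If every client drops, the round is
#' skipped and the previous global model is retained. Deterministic under
#' `config$seed`.
#'
#' @param config An [fl_config()].
#' @param client_datasets Named list of `list(X, y, client_id)` per client.
#' @param clf_config A [classifier_config()] shared by all clients.
#' @param eval_set List with `X`, `y`: a global held-out set, never
#'   partitioned to clients.
#' @return List: `history` (one record per round: participating clients,
#'   global digest, eval accuracy), `model` (final global `caps_model`),
#'   `weights`, `ledger`.
#' @export
run_simulation <- function(config, client_datasets, clf_config,
                           eval_set) {
  stopifnot(inherits(config, "fl_config"))
  if (length(client_datasets) != config$K)
    stop("client_datasets length must equal config$K")
  classes <- sort(unique(unlist(lapply(client_datasets, `[[`, "y"))))
  clf_config$n_classes <- length(classes)
  clf_config$seed <- derive_seed(config$seed, "global-init")
  global_model <- build_classifier(clf_config)
  global_model$classes <- classes
  gw <- flatten_params(global_model$layers)$values
  ledger <- new_ledger()
  history <- list()
  for (t in seq_len(config$rounds)) {
    updates <- list()
    for (k in seq_along(client_datasets)) {
      cd <- client_datasets[[k]]
      cd$client_id <- cd$client_id %||% names(client_datasets)[k] %||%
        paste0("client-", k)
      u <- local_train(cd, gw, clf_config,
                       local_epochs = config$local_epochs, lr = config$lr,
                       batch_size = config$batch_size,
                       seed = derive_seed(config$seed, "round", t,
                                          "client", k),
                       classes = classes)
      u$round <- t
      updates[[length(updates) + 1]] <- u
    }
    inj <- inject_failures(updates, config$dropout_rate, config$noise_rate,
                           config$noise_sigma,
                           seed = derive_seed(config$seed, "failures", t))
    if (length(inj$updates) == 0) {
      warning("round ", t, ": all clients dropped; retaining previous global")
      history[[t]] <- list(round = t, participants = character(0),
                           digest = digest_weights(gw), accuracy = NA_real_,
                           injections = inj$log, skipped = TRUE)
      next
    }
    ups <- inj$updates
    if (isTRUE(config$dp$enabled))
      ups <- lapply(seq_along(ups), function(i)
        dp_noise(ups[[i]], config$dp$epsilon, config$dp$delta,
                 config$dp$clip_norm,
                 seed = derive_seed(config$seed, "dp", t, i)))
    gw <- fedavg(ups)
    dg <- digest_weights(gw)
    ledger <- append_block(ledger, round = t, payload_digest = dg,
                           validator_id = ledger$authority_set[
                             (t - 1) %% length(ledger$authority_set) + 1])
    global_model$layers <- unflatten_params(global_model$layers, gw)
    acc <- NA_real_
    if (!is.null(eval_set)) {
      pr <- predict_capsule(global_model, eval_set$X)
      acc <- mean(pr$label == as.character(eval_set$y))
    }
    history[[t]] <- list(round = t,
                         participants = vapply(ups, `[[`, "", "client_id"),
                         digest = dg, accuracy = acc, injections = inj$log,
                         skipped = FALSE)
  }
  list(history = history, model = global_model, weights = gw,
       ledger = ledger)
}
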