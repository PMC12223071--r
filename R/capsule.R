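# Capsule classification head with squashing and routing-by-agreement, fed
# either by HGBOA-selected fused feature vectors (default) or by a small
# residual convolutional backbone on raw images.

#' Squashing nonlinearity
#'
#' `v = (|s|^2 / (1 + |s|^2)) * s / |s|`; zero maps to zero, direction is
#' preserved, and `|v| < 1` always.
#'
#' @param s Numeric vector.
#' @return Squashed vector.
#' @export
#' @examples
#' sqrt(sum(squash(c(1, 0))^2)) # 0.5
squash <- function(s) {
  if (!all(is.finite(s))) stop("non-finite input")
  r2 <- sum(s^2)
  if (r2 == 0) return(s * 0)
  s * sqrt(r2) / (1 + r2)
}

# row-wise squash of an n x d matrix; returns value + norms for backprop
squash_rows <- function(S) {
  r2 <- rowSums(S^2)
  r <- sqrt(r2)
  f <- ifelse(r2 > 0, r / (1 + r2), 0)
  list(V = S * f, r = r, f = f)
}

# backprop through row-wise squash: dS from dV
squash_rows_backward <- function(S, sq, dV) {
  r <- sq$r
  ok <- r > 1e-12
  h <- sq$f                                  # r / (1 + r^2)
  hp <- ifelse(ok, (1 - r^2) / (1 + r^2)^2, 0) # dh/dr
  shat <- S
  shat[ok, ] <- S[ok, , drop = FALSE] / r[ok]
  shat[!ok, ] <- 0
  dot <- rowSums(shat * dV)
  dV * h + shat * (hp * r * dot)
}

#' Dynamic routing by agreement
#'
#' Logits start at zero; couplings are a softmax over parent capsules, so
#' each child's couplings sum to 1; parent inputs are coupling-weighted sums
#' of the child prediction vectors, squashed; logits grow with the
#' prediction-output agreement. Deterministic.
#'
#' @param u_hat Array `[n_children, parent_dim, n_parents]` of prediction
#'   vectors (single sample) .
#' @param iters Routing iterations (>= 1).
#' @return List: `v` (`parent_dim x n_parents` outputs), `c` (final
#'   couplings, `n_children x n_parents`), `b` (final logits).
#' @export
dynamic_routing <- function(u_hat, iters = 3) {
  if (iters < 1) stop("iters must be >= 1")
  d <- dim(u_hat)
  if (length(d) != 3) stop("u_hat must be [children, dim, parents]")
  P <- d[1]; dd <- d[2]; J <- d[3]
  b <- matrix(0, P, J)
  v <- matrix(0, dd, J)
  cc <- NULL
  for (it in seq_len(iters)) {
    e <- exp(b - apply(b, 1, max))
    cc <- e / rowSums(e)
    for (j in seq_len(J)) {
      s <- colSums(u_hat[, , j, drop = FALSE][, , 1] * cc[, j])
      v[, j] <- squash(s)
    }
    for (j in seq_len(J))
      b[, j] <- b[, j] + as.vector(u_hat[, , j, drop = FALSE][, , 1] %*% v[, j])
  }
  list(v = v, c = cc, b = b)
}

#' Capsule classifier configuration
#'
#' @param mode `"features"` (capsules over a fused feature vector, the
#'   default pipeline path) or `"image"` (small residual backbone).
#' @param input_dim Feature-vector length (features mode).
#' @param input_size Square image side (image mode).
#' @param n_primary,primary_dim Primary capsule count and dimension.
#' @param n_classes,digit_dim Class capsule count and dimension.
#' @param routing_iters Routing iterations (default 3).
#' @param backbone `"tiny-res"` (two residual stages) or
#'   `"paper-like-res50"` (deeper stack; CPU-heavy, provided for parity).
#' @param seed Initialization seed.
#' @return A `classifier_config`.
#' @export
classifier_config <- function(mode = c("features", "image"), input_dim = 16,
                              input_size = 64, n_primary = 8, primary_dim = 8,
                              n_classes = 2, digit_dim = 8, routing_iters = 3,
                              backbone = c("tiny-res", "paper-like-res50"),
                              seed = 1L) {
  mode <- match.arg(mode)
  if (routing_iters < 1) stop("routing_iters must be >= 1")
  if (n_classes < 2) stop("need >= 2 classes")
  structure(list(mode = mode, input_dim = as.integer(input_dim),
                 input_size = as.integer(input_size),
                 n_primary = as.integer(n_primary),
                 primary_dim = as.integer(primary_dim),
                 n_classes = as.integer(n_classes),
                 digit_dim = as.integer(digit_dim),
                 routing_iters = as.integer(routing_iters),
                 backbone = match.arg(backbone), seed = as.integer(seed)),
            class = "classifier_config")
}

backbone_channels <- function(config) {
  if (config$backbone == "tiny-res") c(8L, 16L) else c(16L, 32L, 64L, 128L)
}

#' Build a capsule classifier
#'
#' Features mode: linear primary-capsule projection -> squash -> per-capsule
#' prediction matrices -> dynamic routing into class capsules. Image mode
#' prepends a residual convolutional backbone whose last stage is globally
#' average-pooled into the feature vector. Prediction = class of maximum
#' capsule norm; the norm is the confidence.
#'
#' @param config A [classifier_config()].
#' @return A `caps_model`.
#' @export
build_classifier <- function(config) {
  stopifnot(inherits(config, "classifier_config"))
  with_seed(config$seed, {
    layers <- list()
    feat_dim <- config$input_dim
    if (config$mode == "image") {
      ch <- backbone_channels(config)
      bb <- list(stem = conv_init(3L, 1L, ch[1]), stem_bn = bn_init(ch[1]))
      cin <- ch[1]
      for (k in seq_along(ch)[-1]) {
        bb[[paste0("res", k)]] <- res_block_init(cin, ch[k])
        cin <- ch[k]
      }
      layers$backbone <- bb
      feat_dim <- cin
    }
    layers$fc <- fc_init(feat_dim, config$n_primary * config$primary_dim)
    caps <- list()
    sd <- sqrt(1 / config$primary_dim)
    for (i in seq_len(config$n_primary))
      caps[[paste0("c", i)]] <- list(
        W = matrix(stats::rnorm(config$primary_dim * config$digit_dim *
                                  config$n_classes, 0, sd),
                   config$primary_dim,
                   config$digit_dim * config$n_classes))
    layers$caps <- caps
    structure(list(config = config, layers = layers,
                   classes = paste0("class", seq_len(config$n_classes))),
              class = "caps_model")
  })
}

# backbone forward for a batch of images (list of matrices); returns pooled
# features (n x C) and caches
backbone_forward <- function(model, images, train = FALSE) {
  cfg <- model$config
  bb <- model$layers$backbone
  B <- length(images)
  x <- stack_images(images)
  shape <- list(H = cfg$input_size, W = cfg$input_size, B = B)
  c0 <- conv_forward(bb$stem, x, shape)
  b0 <- bn_forward(bb$stem_bn, c0$y, train); bb$stem_bn <- b0$layer
  r0 <- relu_forward(b0$y)
  z <- r0$y
  caches <- list(c0 = c0, b0 = b0, r0 = r0, stages = list(),
                 shapes = list(shape))
  res_names <- grep("^res", names(bb), value = TRUE)
  for (nm in res_names) {
    mp <- maxpool_forward(z, shape)
    shape <- list(H = shape$H %/% 2L, W = shape$W %/% 2L, B = B)
    rf <- res_block_forward(bb[[nm]], mp$y, shape, train)
    bb[[nm]] <- rf$block
    caches$stages[[nm]] <- list(pool = mp$cache, block = rf$cache,
                                shape = shape)
    z <- rf$y
  }
  # global average pooling per channel per sample
  npix <- shape$H * shape$W
  feats <- matrix(0, B, ncol(z))
  for (b in seq_len(B))
    feats[b, ] <- colMeans(z[((b - 1) * npix + 1):(b * npix), , drop = FALSE])
  caches$final_shape <- shape
  caches$nz <- nrow(z)
  model$layers$backbone <- bb
  list(feats = feats, model = model, caches = caches)
}

backbone_backward <- function(model, caches, dfeats) {
  bb <- model$layers$backbone
  shape <- caches$final_shape
  npix <- shape$H * shape$W
  B <- shape$B
  dz <- matrix(0, caches$nz, ncol(dfeats))
  for (b in seq_len(B))
    dz[((b - 1) * npix + 1):(b * npix), ] <-
      matrix(dfeats[b, ] / npix, npix, ncol(dfeats), byrow = TRUE)
  g <- list()
  res_names <- rev(grep("^res", names(bb), value = TRUE))
  for (nm in res_names) {
    st <- caches$stages[[nm]]
    rb <- res_block_backward(bb[[nm]], st$block, dz, st$shape)
    g[[nm]] <- rb$grads
    dz <- maxpool_backward(st$pool, rb$dx, ncol(rb$dx))
  }
  dr <- relu_backward(caches$r0$cache, dz)
  db <- bn_backward(bb$stem_bn, caches$b0$cache, dr)
  dc <- conv_backward(bb$stem, caches$c0$cache, db$dx, caches$shapes[[1]])
  out <- list(stem = dc$grads, stem_bn = db$grads)
  for (nm in grep("^res", names(bb), value = TRUE)) out[[nm]] <- g[[nm]]
  out
}

# full forward over a feature matrix X (n x d) or list of images.
# Returns class-capsule norms plus everything needed for backprop.
caps_forward <- function(model, X, train = FALSE) {
  cfg <- model$config
  bk_cache <- NULL
  if (cfg$mode == "image") {
    bf <- backbone_forward(model, X, train)
    model <- bf$model
    bk_cache <- bf$caches
    X <- bf$feats
  }
  fcf <- fc_forward(model$layers$fc, X)
  n <- nrow(X)
  P <- cfg$n_primary; pd <- cfg$primary_dim
  dd <- cfg$digit_dim; J <- cfg$n_classes
  prim <- vector("list", P) # squashed primary outputs + caches
  A <- array(0, c(n, P, dd, J)) # u_hat
  for (i in seq_len(P)) {
    Si <- fcf$y[, ((i - 1) * pd + 1):(i * pd), drop = FALSE]
    sq <- squash_rows(Si)
    prim[[i]] <- list(S = Si, sq = sq)
    A[, i, , ] <- array(sq$V %*% model$layers$caps[[i]]$W, c(n, dd, J))

  }
  # batched routing-by-agreement
  b <- array(0, c(n, P, J))
  cc <- NULL
  V <- array(0, c(n, dd, J))
  sqs <- vector("list", J)
  S_par <- array(0, c(n, dd, J))
  for (it in seq_len(cfg$routing_iters)) {
    bmax <- apply(b, c(1, 2), max)
    e <- exp(b - array(bmax, c(n, P, J)))
    cc <- e / array(apply(e, c(1, 2), sum), c(n, P, J))
    for (j in seq_len(J)) {
      S <- matrix(0, n, dd)
      for (i in seq_len(P))
        S <- S + matrix(A[, i, , j], n, dd) * cc[, i, j]
      sqj <- squash_rows(S)
      S_par[, , j] <- S
      V[, , j] <- sqj$V
      sqs[[j]] <- sqj
    }
    if (it < cfg$routing_iters)
      for (j in seq_len(J)) for (i in seq_len(P))
        b[, i, j] <- b[, i, j] +
          rowSums(matrix(A[, i, , j], n, dd) * matrix(V[, , j], n, dd))
  }
  norms <- sqrt(apply(V^2, c(1, 3), sum))
  list(model = model, norms = norms,
       cache = list(X = X, fc = fcf, prim = prim, A = A, cc = cc,
                    S_par = S_par, V = V, sqs = sqs, bk = bk_cache))
}

# margin loss and gradient w.r.t. class-capsule norms
margin_loss <- function(norms, y_idx, m_pos = 0.9, m_neg = 0.1, lam = 0.5) {
  n <- nrow(norms); J <- ncol(norms)
  Tm <- matrix(0, n, J)
  Tm[cbind(seq_len(n), y_idx)] <- 1
  pos <- pmax(0, m_pos - norms)
  neg <- pmax(0, norms - m_neg)
  loss <- sum(Tm * pos^2 + lam * (1 - Tm) * neg^2) / n
  dnorm <- (Tm * (-2 * pos) + lam * (1 - Tm) * 2 * neg) / n
  list(loss = loss, dnorm = dnorm)
}

caps_backward <- function(model, cache, dnorm) {
  cfg <- model$config
  n <- nrow(dnorm)
  P <- cfg$n_primary; pd <- cfg$primary_dim
  dd <- cfg$digit_dim; J <- cfg$n_classes
  dA <- array(0, c(n, P, dd, J))
  for (j in seq_len(J)) {
    Vj <- matrix(cache$V[, , j], n, dd)
    nrm <- sqrt(rowSums(Vj^2))
    vhat <- Vj
    ok <- nrm > 1e-12
    vhat[ok, ] <- Vj[ok, , drop = FALSE] / nrm[ok]
    vhat[!ok, ] <- 0
    dV <- vhat * dnorm[, j]
    dS <- squash_rows_backward(matrix(cache$S_par[, , j], n, dd),
                               cache$sqs[[j]], dV)
    for (i in seq_len(P)) dA[, i, , j] <- dS * cache$cc[, i, j]
  }
  dU <- matrix(0, n, P * pd)
  gcaps <- list()
  for (i in seq_len(P)) {
    dUhat_i <- matrix(dA[, i, , ], n, dd * J)
    Wi <- model$layers$caps[[i]]$W
    Vi <- cache$prim[[i]]$sq$V
    gcaps[[paste0("c", i)]] <- list(W = crossprod(Vi, dUhat_i))
    dVi <- tcrossprod(dUhat_i, Wi)
    dSi <- squash_rows_backward(cache$prim[[i]]$S, cache$prim[[i]]$sq, dVi)
    dU[, ((i - 1) * pd + 1):(i * pd)] <- dSi
  }
  fb <- fc_backward(model$layers$fc, cache$fc$cache, dU)
  grads <- list()
  if (cfg$mode == "image")
    grads$backbone <- backbone_backward(model, cache$bk, fb$dx)
  grads$fc <- fb$grads
  grads$caps <- gcaps
  grads
}

#' Train a capsule classifier
#'
#' Margin loss per class (`m+ = 0.9`, `m- = 0.1`, `lambda = 0.5`), Adam
#' updates, deterministic under `seed`. Routing couplings are treated as
#' constants within each backward pass.
#'
#' @param X Feature matrix (features mode) or list of image matrices (image
#'   mode).
#' @param y Class labels (factor or coercible; >= 2 classes present unless
#'   resuming federated training, see `allow_single_class`).
#' @param config A [classifier_config()].
#' @param epochs Training epochs (0 returns the initialization).
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param seed Master seed.
#' @param init_params Optional flat parameter vector to resume from.
#' @param classes Optional fixed class-level ordering (required when `y`
#'   lacks some classes, e.g. a skewed federated client).
#' @param allow_single_class Permit single-class local data (federated
#'   clients); standalone training rejects it.
#' @return List: `model`, `history` (loss and training accuracy per epoch),
#'   `params` (flat vector).
#' @export
train_classifier <- function(X, y, config = classifier_config(),
                             epochs = 10, lr = 1e-3, batch_size = 16,
                             seed = 1L, init_params = NULL, classes = NULL,
                             allow_single_class = FALSE) {
  y <- as.character(y)
  classes <- classes %||% sort(unique(y))
  if (length(classes) < 2 && !allow_single_class)
    stop("need >= 2 classes")
  if (length(classes) != config$n_classes)
    config$n_classes <- length(classes)
  config$seed <- derive_seed(seed, "init")
  model <- build_classifier(config)
  model$classes <- classes
  if (!is.null(init_params))
    model$layers <- unflatten_params(model$layers, init_params)
  fp <- flatten_params(model$layers)
  opt <- adam_init(length(fp$values))
  y_idx <- match(y, classes)
  n <- if (is.matrix(X)) nrow(X) else length(X)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, "epoch", ep), sample(n))
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1, n, batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      Xb <- if (is.matrix(X)) X[idx, , drop = FALSE] else X[idx]
      fw <- caps_forward(model, Xb, train = TRUE)
      model <- fw$model
      ml <- margin_loss(fw$norms, y_idx[idx])
      if (!is.finite(ml$loss)) stop("non-finite loss at epoch ", ep)
      grads <- caps_backward(model, fw$cache, ml$dnorm)
      gflat <- flatten_params(grads)$values
      st <- adam_step(opt, fp$values, gflat, lr)
      opt <- st$state
      fp$values <- st$params
      model$layers <- unflatten_params(model$layers, fp$values)
      ep_loss <- ep_loss + ml$loss * length(idx)
      ep_correct <- ep_correct +
        sum(max.col(fw$norms, ties.method = "first") == y_idx[idx])
    }
    history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / n,
                                         accuracy = ep_correct / n))
  }
  list(model = model, history = history, params = fp$values)
}

#' Predict labels and capsule-norm confidences
#'
#' @param model A trained `caps_model`.
#' @param X Feature matrix or list of images, matching the model's mode.
#' @return List: `label` (character vector), `confidence` (matrix of
#'   per-class capsule norms in `[0, 1)`), ties broken toward the lowest
#'   class index.
#' @export
predict_capsule <- function(model, X) {
  fw <- caps_forward(model, X, train = FALSE)
  idx <- max.col(fw$norms, ties.method = "first")
  colnames(fw$norms) <- model$classes
  list(label = model$classes[idx], confidence = fw$norms)
}

#' Deep-feature extractor from the classifier backbone
#'
#' Builds the image-mode backbone (deterministic under `seed`) and exposes
#' its globally average-pooled last convolutional stage as a feature vector.
#'
#' @param input_size Square image side.
#' @param seed Initialization seed.
#' @return A function `image -> named numeric vector`.
#' @export
deep_feature_extractor <- function(input_size = 64, seed = 1L) {
  cfg <- classifier_config(mode = "image", input_size = input_size,
                           seed = seed)
  model <- build_classifier(cfg)
  function(image) {
    bf <- backbone_forward(model, list(image), train = FALSE)
    stats::setNames(as.numeric(bf$feats),
                    paste0("gap", seq_len(ncol(bf$feats))))
  }
}
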