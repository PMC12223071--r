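# Minimal dense/convolutional layer kernels with explicit backprop.
#
# Feature maps are stored as matrices with rows ordered (batch-major, then
# pixel in column-major (row fastest) order) and one column per channel:
#   row(b, r, c) = (b-1)*H*W + (c-1)*H + r
# Convolutions are im2col gathers followed by one BLAS matrix product; all
# gather index tables are precomputed per (H, W, B, k) and cached.

.idx_cache <- new.env(parent = emptyenv())

# index table mapping each (output pixel, kernel offset) to a source row of
# the feature matrix, with out-of-image positions pointing at a zero row
# (B*H*W + 1). Offsets enumerate dr fastest, matching conv weight layout.
conv_idx <- function(H, W, B, k) {
  key <- paste("cv", H, W, B, k, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- (k - 1L) %/% 2L
  off <- as.matrix(expand.grid(dr = -p:p, dc = -p:p))
  r <- rep(seq_len(H), W)
  c <- rep(seq_len(W), each = H)
  zero_row <- B * H * W + 1L
  idx1 <- matrix(0L, H * W, k * k)
  for (o in seq_len(nrow(off))) {
    rr <- r + off[o, 1]; cc <- c + off[o, 2]
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    idx1[, o] <- ifelse(ok, (cc - 1L) * H + rr, zero_row)
  }
  idx <- matrix(0L, B * H * W, k * k)
  for (b in seq_len(B)) {
    block <- idx1
    inb <- block != zero_row
    block[inb] <- block[inb] + (b - 1L) * H * W
    idx[((b - 1) * H * W + 1):(b * H * W), ] <- block
  }
  .idx_cache[[key]] <- idx
  idx
}

im2col <- function(x, H, W, B, k) {
  # x: (B*H*W) x C matrix -> (B*H*W) x (k*k*C) patch matrix
  C <- ncol(x)
  idx <- conv_idx(H, W, B, k)
  xz <- rbind(x, 0)
  P <- matrix(0, nrow(x), k * k * C)
  K <- k * k
  for (ci in seq_len(C))
    P[, ((ci - 1) * K + 1):(ci * K)] <- xz[, ci][idx]
  P
}

# --- conv2d (same padding, odd k) ------------------------------------------

conv_init <- function(k, cin, cout) {
  # He-normal fan-in initialization; draws from the active RNG stream
  sd <- sqrt(2 / (k * k * cin))
  list(W = matrix(stats::rnorm(k * k * cin * cout, 0, sd), k * k * cin, cout),
       b = numeric(cout), k = k, cin = cin, cout = cout)
}

conv_forward <- function(layer, x, shape) {
  P <- im2col(x, shape$H, shape$W, shape$B, layer$k)
  y <- P %*% layer$W
  y <- sweep(y, 2, layer$b, "+")
  list(y = y, cache = list(P = P, x_dim = dim(x)))
}

conv_backward <- function(layer, cache, dy, shape) {
  dW <- crossprod(cache$P, dy)
  db <- colSums(dy)
  # grad w.r.t. input: correlate dy with flipped kernels
  k <- layer$k; K <- k * k
  Wb <- matrix(0, K * layer$cout, layer$cin)
  for (ci in seq_len(layer$cin)) for (co in seq_len(layer$cout))
    Wb[((co - 1) * K + 1):(co * K), ci] <-
      rev(layer$W[((ci - 1) * K + 1):(ci * K), co])
  Pg <- im2col(dy, shape$H, shape$W, shape$B, k)
  dx <- Pg %*% Wb
  list(dx = dx, grads = list(W = dW, b = db))
}

# --- batch normalization (per channel) -------------------------------------

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c), momentum = 0.1,
       eps = 1e-5)
}

bn_forward <- function(layer, x, train = TRUE) {
  if (train) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    v <- colMeans(xc^2)
    layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
    layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * v
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
    xc <- sweep(x, 2, mu)
  }
  inv <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(xc, 2, inv, "*")
  y <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
  list(y = y, layer = layer,
       cache = list(xhat = xhat, inv = inv, train = train))
}

bn_backward <- function(layer, cache, dy) {
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, layer$gamma, "*")
  if (cache$train) {
    n <- nrow(dy)
    t1 <- sweep(dxhat, 2, colMeans(dxhat))
    t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
    dx <- sweep(t1 - t2, 2, cache$inv, "*")
  } else {
    dx <- sweep(dxhat, 2, cache$inv, "*")
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

relu_forward <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_backward <- function(cache, dy) dy * cache

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- 2x2 max pooling --------------------------------------------------------

pool_idx <- function(H, W, B) {
  key <- paste("mp", H, W, B, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- H %/% 2L; Wo <- W %/% 2L
  r <- rep(seq(1L, H, 2L), Wo)
  c <- rep(seq(1L, W, 2L), each = Ho)
  base <- (c - 1L) * H + r
  per_b <- function(dr, dc) (c + dc - 1L) * H + (r + dr)
  sub <- lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)),
                function(d) {
                  v <- per_b(d[1], d[2])
                  as.vector(outer(v, (seq_len(B) - 1L) * H * W, "+"))
                })
  .idx_cache[[key]] <- sub
  sub
}

maxpool_forward <- function(x, shape) {
  sub <- pool_idx(shape$H, shape$W, shape$B)
  x1 <- x[sub[[1]], , drop = FALSE]; x2 <- x[sub[[2]], , drop = FALSE]
  x3 <- x[sub[[3]], , drop = FALSE]; x4 <- x[sub[[4]], , drop = FALSE]
  y <- pmax(x1, x2, x3, x4)
  sel <- 1L + (x2 == y & x1 < y) * 1L
  sel[x3 == y & x1 < y & x2 < y] <- 3L
  sel[x4 == y & x1 < y & x2 < y & x3 < y] <- 4L
  list(y = y, cache = list(sel = sel, sub = sub, n_in = nrow(x)))
}

maxpool_backward <- function(cache, dy, ncol_x) {
  dx <- matrix(0, cache$n_in, ncol_x)
  for (q in 1:4) {
    m <- dy * (cache$sel == q)
    dx[cache$sub[[q]], ] <- dx[cache$sub[[q]], ] + m
  }
  dx
}

# --- 2x2 stride-2 transposed convolution -----------------------------------

tconv_init <- function(cin, cout) {
  sd <- sqrt(2 / cin)
  list(W = matrix(stats::rnorm(cin * 4 * cout, 0, sd), cin, 4 * cout),
       b = numeric(cout), cin = cin, cout = cout)
}

tconv_idx <- function(H, W, B) {
  # maps input pixel rows to the 4 output rows they populate (2H x 2W out)
  key <- paste("tc", H, W, B, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- 2L * H; Wo <- 2L * W
  r <- rep(seq_len(H), W)
  c <- rep(seq_len(W), each = H)
  out <- lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)),
                function(d) {
                  v <- (2L * c - 1L + d[2] - 1L) * Ho + (2L * r - 1L + d[1])
                  as.vector(outer(v, (seq_len(B) - 1L) * Ho * Wo, "+"))
                })
  .idx_cache[[key]] <- out
  out
}

tconv_forward <- function(layer, x, shape) {
  Y4 <- x %*% layer$W # (B*H*W) x (4*cout), block q = output sub-position q
  idx <- tconv_idx(shape$H, shape$W, shape$B)
  y <- matrix(0, shape$B * 4L * shape$H * shape$W, layer$cout)
  co <- layer$cout
  for (q in 1:4)
    y[idx[[q]], ] <- Y4[, ((q - 1) * co + 1):(q * co), drop = FALSE]
  y <- sweep(y, 2, layer$b, "+")
  list(y = y, cache = list(x = x, idx = idx))
}

tconv_backward <- function(layer, cache, dy) {
  co <- layer$cout
  dY4 <- matrix(0, nrow(cache$x), 4 * co)
  for (q in 1:4)
    dY4[, ((q - 1) * co + 1):(q * co)] <- dy[cache$idx[[q]], , drop = FALSE]
  list(dx = dY4 %*% t(layer$W),
       grads = list(W = crossprod(cache$x, dY4), b = colSums(dy)))
}

# --- dense (fully connected) ------------------------------------------------

fc_init <- function(cin, cout) {
  sd <- sqrt(2 / cin)
  list(W = matrix(stats::rnorm(cin * cout, 0, sd), cin, cout),
       b = numeric(cout))
}

fc_forward <- function(layer, x) {
  list(y = sweep(x %*% layer$W, 2, layer$b, "+"), cache = x)
}

fc_backward <- function(layer, cache, dy) {
  list(dx = tcrossprod(dy, layer$W),
       grads = list(W = crossprod(cache, dy), b = colSums(dy)))
}

# --- parameter (un)flattening and Adam --------------------------------------

# collect all numeric leaves named W/b/gamma/beta from a nested layer list,
# in deterministic (list-order) traversal; running BN statistics are buffers,
# not parameters, and are excluded.
PARAM_NAMES <- c("W", "b", "gamma", "beta")

flatten_params <- function(layers) {
  out <- numeric(0)
  registry <- list()
  walk <- function(node, path) {
    if (is.list(node)) {
      for (nm in names(node)) {
        child <- node[[nm]]
        if (nm %in% PARAM_NAMES && is.numeric(child)) {
          registry[[length(registry) + 1]] <<-
            list(name = paste(c(path, nm), collapse = "/"),
                 dim = dim(child) %||% length(child),
                 offset = length(out))
          out <<- c(out, as.numeric(child))
        } else if (is.list(child)) {
          walk(child, c(path, nm))
        }
      }
    }
  }
  walk(layers, character(0))
  list(values = out, registry = registry)
}

unflatten_params <- function(layers, values) {
  pos <- 0
  walk <- function(node) {
    for (nm in names(node)) {
      child <- node[[nm]]
      if (nm %in% PARAM_NAMES && is.numeric(child)) {
        n <- length(child)
        repl <- values[(pos + 1):(pos + n)]
        pos <<- pos + n
        if (!is.null(dim(child))) dim(repl) <- dim(child)
        node[[nm]] <- repl
      } else if (is.list(child)) {
        node[[nm]] <- walk(child)
      }
    }
    node
  }
  out <- walk(layers)
  stopifnot(pos == length(values))
  out
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0,
                              beta1 = 0.9, beta2 = 0.999, eps = 1e-8)

adam_step <- function(state, params, grads, lr) {
  stopifnot(length(grads) == length(params))
  state$t <- state$t + 1
  state$m <- state$beta1 * state$m + (1 - state$beta1) * grads
  state$v <- state$beta2 * state$v + (1 - state$beta2) * grads^2
  mhat <- state$m / (1 - state$beta1^state$t)
  vhat <- state$v / (1 - state$beta2^state$t)
  list(state = state, params = params - lr * mhat / (sqrt(vhat) + state$eps))
}
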