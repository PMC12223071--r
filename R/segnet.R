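# Small U-Net with residual or dense blocks for pixel-wise tumor probability
# maps, trained under Dice loss. The network runs on the matrix-layout layer
# kernels in nn_core.R; a "tiny" preset (depth 3, base 8) trains on CPU over
# phantoms in minutes.

#' Segmentation network configuration
#'
#' @param depth Number of encoder levels (the bottleneck sits one pooling
#'   below the deepest level).
#' @param base_channels Channels at the first level; doubled per level for
#'   residual blocks.
#' @param block_kind `"residual"` or `"dense"`.
#' @param growth_rate Channels added by each layer of a dense block.
#' @param layers_per_block Layers inside a dense block.
#' @param input_size Square input side; must be divisible by `2^depth`.
#' @param skip_enabled Keep the residual identity skip (set `FALSE` only for
#'   ablation experiments).
#' @param seed Initialization seed.
#' @return A `segnet_config`.
#' @export
segnet_config <- function(depth = 3, base_channels = 8,
                          block_kind = c("residual", "dense"),
                          growth_rate = 4, layers_per_block = 2,
                          input_size = 64, skip_enabled = TRUE, seed = 1L) {
  block_kind <- match.arg(block_kind)
  if (depth < 1) stop("depth must be >= 1")
  if (input_size %% 2^depth != 0)
    stop("input_size must be divisible by 2^depth")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 block_kind = block_kind,
                 growth_rate = as.integer(growth_rate),
                 layers_per_block = as.integer(layers_per_block),
                 input_size = as.integer(input_size),
                 skip_enabled = isTRUE(skip_enabled),
                 seed = as.integer(seed)),
            class = "segnet_config")
}

# --- blocks -----------------------------------------------------------------

res_block_init <- function(cin, cout) {
  list(conv1 = conv_init(3L, cin, cout), bn1 = bn_init(cout),
       conv2 = conv_init(3L, cout, cout), bn2 = bn_init(cout),
       proj = if (cin != cout) conv_init(1L, cin, cout) else NULL)
}

res_block_forward <- function(block, x, shape, train, skip = TRUE) {
  c1 <- conv_forward(block$conv1, x, shape)
  b1 <- bn_forward(block$bn1, c1$y, train); block$bn1 <- b1$layer
  r1 <- relu_forward(b1$y)
  c2 <- conv_forward(block$conv2, r1$y, shape)
  b2 <- bn_forward(block$bn2, c2$y, train); block$bn2 <- b2$layer
  idn <- NULL
  f <- b2$y
  if (skip) {
    idn <- if (is.null(block$proj)) list(y = x, cache = NULL)
           else conv_forward(block$proj, x, shape)
    f <- f + idn$y
  }
  r2 <- relu_forward(f)
  list(y = r2$y, block = block,
       cache = list(c1 = c1, b1 = b1, r1 = r1, c2 = c2, b2 = b2,
                    idn = idn, r2 = r2, skip = skip))
}

res_block_backward <- function(block, cache, dy, shape) {
  d <- relu_backward(cache$r2$cache, dy)
  g <- list()
  dskip <- NULL
  if (cache$skip) {
    if (is.null(block$proj)) {
      dskip <- d
    } else {
      pb <- conv_backward(block$proj, cache$idn$cache, d, shape)
      dskip <- pb$dx
      g$proj <- pb$grads
    }
  } else if (!is.null(block$proj)) {
    # projection parameters exist but are unused in the ablated block:
    # emit zero gradients to keep the flat vectors aligned
    g$proj <- list(W = block$proj$W * 0, b = block$proj$b * 0)
  }
  b2 <- bn_backward(block$bn2, cache$b2$cache, d); g$bn2 <- b2$grads
  c2 <- conv_backward(block$conv2, cache$c2$cache, b2$dx, shape)
  g$conv2 <- c2$grads
  dr1 <- relu_backward(cache$r1$cache, c2$dx)
  b1 <- bn_backward(block$bn1, cache$b1$cache, dr1); g$bn1 <- b1$grads
  c1 <- conv_backward(block$conv1, cache$c1$cache, b1$dx, shape)
  g$conv1 <- c1$grads
  dx <- c1$dx
  if (!is.null(dskip)) dx <- dx + dskip
  # grads ordered to mirror the block's parameter layout
  list(dx = dx, grads = list(conv1 = g$conv1, bn1 = g$bn1, conv2 = g$conv2,
                             bn2 = g$bn2, proj = g$proj))
}

dense_block_init <- function(cin, L, growth) {
  layers <- list()
  ch <- cin
  for (l in seq_len(L)) {
    layers[[paste0("l", l)]] <- list(conv = conv_init(3L, ch, growth),
                                     bn = bn_init(growth))
    ch <- ch + growth
  }
  list(layers = layers)
}

dense_block_forward <- function(block, x, shape, train, skip = TRUE) {
  feats <- x
  caches <- list()
  for (nm in names(block$layers)) {
    ly <- block$layers[[nm]]
    cv <- conv_forward(ly$conv, feats, shape)
    bn <- bn_forward(ly$bn, cv$y, train)
    block$layers[[nm]]$bn <- bn$layer
    rl <- relu_forward(bn$y)
    caches[[nm]] <- list(cv = cv, bn = bn, rl = rl, cin = ncol(feats))
    feats <- cbind(feats, rl$y) # concatenate all preceding layer outputs
  }
  list(y = feats, block = block, cache = caches)
}

dense_block_backward <- function(block, cache, dy, shape) {
  nms <- names(block$layers)
  grads <- stats::setNames(vector("list", length(nms)), nms)
  dfeats <- dy # gradient w.r.t. the running concatenation
  for (nm in rev(nms)) {
    ca <- cache[[nm]]
    growth <- ncol(ca$rl$y)
    n_in <- ca$cin
    d_out <- dfeats[, (n_in + 1):(n_in + growth), drop = FALSE]
    dfeats <- dfeats[, seq_len(n_in), drop = FALSE]
    dr <- relu_backward(ca$rl$cache, d_out)
    db <- bn_backward(block$layers[[nm]]$bn, ca$bn$cache, dr)
    dc <- conv_backward(block$layers[[nm]]$conv, ca$cv$cache, db$dx, shape)
    grads[[nm]] <- list(conv = dc$grads, bn = db$grads)
    dfeats <- dfeats + dc$dx
  }
  list(dx = dfeats, grads = list(layers = grads))
}

block_init <- function(config, cin, cout_target) {
  if (config$block_kind == "residual")
    list(block = res_block_init(cin, cout_target), cout = cout_target)
  else
    list(block = dense_block_init(cin, config$layers_per_block,
                                  config$growth_rate),
         cout = cin + config$layers_per_block * config$growth_rate)
}

block_forward <- function(config, block, x, shape, train) {
  if (config$block_kind == "residual")
    res_block_forward(block, x, shape, train, skip = config$skip_enabled)
  else dense_block_forward(block, x, shape, train)
}

block_backward <- function(config, block, cache, dy, shape) {
  if (config$block_kind == "residual")
    res_block_backward(block, cache, dy, shape)
  else dense_block_backward(block, cache, dy, shape)
}

# --- network ----------------------------------------------------------------

#' Build a segmentation U-Net
#'
#' Encoder: a block per level with 2x2 max pooling between levels; a
#' bottleneck block below the deepest level; decoder: 2x2 transposed
#' convolution, concatenation with the matching encoder output, block; head:
#' 1x1 convolution + sigmoid giving per-pixel tumor probabilities.
#' Initialization is deterministic under `config$seed`.
#'
#' @param config A [segnet_config()].
#' @return A `seg_model` (layers + config).
#' @export
build_segnet <- function(config) {
  stopifnot(inherits(config, "segnet_config"))
  with_seed(config$seed, {
    d <- config$depth
    enc <- list()
    enc_ch <- integer(d)
    cin <- 1L
    for (i in seq_len(d)) {
      tgt <- config$base_channels * 2^(i - 1)
      bi <- block_init(config, cin, tgt)
      enc[[paste0("e", i)]] <- bi$block
      enc_ch[i] <- bi$cout
      cin <- bi$cout
    }
    bott <- block_init(config, enc_ch[d], 2L * enc_ch[d])
    up <- list()
    dec <- list()
    zch <- bott$cout
    for (i in rev(seq_len(d))) {
      up[[paste0("u", i)]] <- tconv_init(zch, enc_ch[i])
      di <- block_init(config, 2L * enc_ch[i], enc_ch[i])
      dec[[paste0("d", i)]] <- di$block
      zch <- di$cout
    }
    head <- conv_init(1L, zch, 1L)
    structure(list(config = config, enc_ch = enc_ch,
                   layers = list(enc = enc, bott = bott$block, up = up,
                                 dec = dec, head = head)),
              class = "seg_model")
  })
}

#' Analytic parameter count for a segmentation config
#'
#' @param config A [segnet_config()].
#' @return Integer parameter count (weights, biases, BN scale/shift).
#' @export
segnet_param_count <- function(config) {
  conv_n <- function(k, cin, cout) k * k * cin * cout + cout
  bn_n <- function(c) 2 * c
  block_n <- function(cin, tgt) {
    if (config$block_kind == "residual") {
      n <- conv_n(3, cin, tgt) + bn_n(tgt) + conv_n(3, tgt, tgt) + bn_n(tgt)
      if (cin != tgt) n <- n + conv_n(1, cin, tgt)
      list(n = n, cout = tgt)
    } else {
      n <- 0; ch <- cin
      for (l in seq_len(config$layers_per_block)) {
        n <- n + conv_n(3, ch, config$growth_rate) + bn_n(config$growth_rate)
        ch <- ch + config$growth_rate
      }
      list(n = n, cout = ch)
    }
  }
  total <- 0
  cin <- 1; enc_ch <- integer(config$depth)
  for (i in seq_len(config$depth)) {
    b <- block_n(cin, config$base_channels * 2^(i - 1))
    total <- total + b$n; enc_ch[i] <- b$cout; cin <- b$cout
  }
  b <- block_n(enc_ch[config$depth], 2 * enc_ch[config$depth])
  total <- total + b$n
  zch <- b$cout
  for (i in rev(seq_len(config$depth))) {
    total <- total + zch * 4 * enc_ch[i] + enc_ch[i] # transposed conv
    db <- block_n(2 * enc_ch[i], enc_ch[i])
    total <- total + db$n
    zch <- db$cout
  }
  total + zch * 1 + 1 # 1x1 head
}

segnet_forward <- function(model, x, B, train = FALSE) {
  cfg <- model$config
  L <- model$layers
  H <- cfg$input_size
  shape <- list(H = H, W = H, B = B)
  caches <- list(enc = list(), pools = list(), up = list(), dec = list())
  skips <- list()
  z <- x
  for (i in seq_len(cfg$depth)) {
    nm <- paste0("e", i)
    bf <- block_forward(cfg, L$enc[[nm]], z, shape, train)
    L$enc[[nm]] <- bf$block
    caches$enc[[nm]] <- bf$cache
    caches$shape_enc[[nm]] <- shape
    skips[[i]] <- bf$y
    z <- bf$y
    if (i < cfg$depth) {
      mp <- maxpool_forward(z, shape)
      caches$pools[[nm]] <- mp$cache
      z <- mp$y
      shape <- list(H = shape$H %/% 2L, W = shape$W %/% 2L, B = B)
    }
  }
  mp <- maxpool_forward(z, shape)
  caches$pool_bott <- mp$cache
  caches$shape_prebott <- shape
  shape <- list(H = shape$H %/% 2L, W = shape$W %/% 2L, B = B)
  bf <- block_forward(cfg, L$bott, mp$y, shape, train)
  L$bott <- bf$block
  caches$bott <- bf$cache
  caches$shape_bott <- shape
  z <- bf$y
  for (i in rev(seq_len(cfg$depth))) {
    nm <- paste0("u", i)
    tf <- tconv_forward(L$up[[nm]], z, shape)
    caches$up[[nm]] <- tf$cache
    shape <- list(H = shape$H * 2L, W = shape$W * 2L, B = B)
    cat_in <- cbind(tf$y, skips[[i]])
    caches$ncol_up[[nm]] <- ncol(tf$y)
    dm <- paste0("d", i)
    bf <- block_forward(cfg, L$dec[[dm]], cat_in, shape, train)
    L$dec[[dm]] <- bf$block
    caches$dec[[dm]] <- bf$cache
    caches$shape_dec[[dm]] <- shape
    z <- bf$y
  }
  hd <- conv_forward(L$head, z, shape)
  y <- sigmoid(hd$y)
  caches$head <- hd$cache
  caches$head_y <- y
  model$layers <- L
  list(y = y, model = model, caches = caches)
}

segnet_backward <- function(model, caches, dy_prob) {
  cfg <- model$config
  L <- model$layers
  # through sigmoid head
  dz <- dy_prob * caches$head_y * (1 - caches$head_y)
  g <- list(enc = list(), bott = NULL, up = list(), dec = list(), head = NULL)
  shape <- caches$shape_dec[["d1"]]
  hb <- conv_backward(L$head, caches$head, dz, shape)
  g$head <- hb$grads
  d <- hb$dx
  dskips <- list()
  for (i in seq_len(cfg$depth)) {
    dm <- paste0("d", i); nm <- paste0("u", i)
    shape <- caches$shape_dec[[dm]]
    bb <- block_backward(cfg, L$dec[[dm]], caches$dec[[dm]], d, shape)
    g$dec[[dm]] <- bb$grads
    ncu <- caches$ncol_up[[nm]]
    d_up <- bb$dx[, seq_len(ncu), drop = FALSE]
    dskips[[i]] <- bb$dx[, (ncu + 1):ncol(bb$dx), drop = FALSE]
    tb <- tconv_backward(L$up[[nm]], caches$up[[nm]], d_up)
    g$up[[nm]] <- tb$grads
    d <- tb$dx
  }
  shape <- caches$shape_bott
  bb <- block_backward(cfg, L$bott, caches$bott, d, shape)
  g$bott <- bb$grads
  d <- maxpool_backward(caches$pool_bott, bb$dx, ncol(bb$dx))
  for (i in rev(seq_len(cfg$depth))) {
    nm <- paste0("e", i)
    d <- d + dskips[[i]]
    shape <- caches$shape_enc[[nm]]
    bb <- block_backward(cfg, L$enc[[nm]], caches$enc[[nm]], d, shape)
    g$enc[[nm]] <- bb$grads
    d <- bb$dx
    if (i > 1) {
      pm <- paste0("e", i - 1)
      d <- maxpool_backward(caches$pools[[pm]], d, ncol(d))
    }
  }
  # mirror the layer ordering: enc blocks in order e1..ed, bott, up/dec pairs
  list(grads = list(enc = g$enc[paste0("e", seq_len(cfg$depth))],
                    bott = g$bott,
                    up = g$up[paste0("u", rev(seq_len(cfg$depth)))],
                    dec = g$dec[paste0("d", rev(seq_len(cfg$depth)))],
                    head = g$head))
}

#' Soft Dice loss
#'
#' `1 - 2 sum(p g) / (sum(p^2) + sum(g^2) + eps)`. The small `eps` guards the
#' empty-mask case (both sums zero), where the loss is defined as 0 for an
#' all-zero prediction on an all-zero truth.
#'
#' @param pred Predicted probabilities (any numeric shape).
#' @param truth Binary ground truth of the same shape.
#' @param eps Smoothing constant.
#' @return Scalar in `[0, 1]`.
#' @export
dice_loss <- function(pred, truth, eps = 1e-6) {
  if (length(pred) != length(truth)) stop("shape mismatch")
  p <- as.numeric(pred); g <- as.numeric(truth)
  1 - 2 * sum(p * g) / (sum(p^2) + sum(g^2) + eps)
}

# gradient of dice_loss w.r.t. pred
dice_loss_grad <- function(pred, truth, eps = 1e-6) {
  p <- as.numeric(pred); g <- as.numeric(truth)
  denom <- sum(p^2) + sum(g^2) + eps
  num <- 2 * sum(p * g)
  grad <- -(2 * g * denom - num * 2 * p) / denom^2
  array(grad, dim(pred) %||% length(pred))
}

# stack scans into the matrix layout expected by the layer kernels
stack_images <- function(images) {
  B <- length(images)
  n <- length(images[[1]])
  x <- matrix(0, B * n, 1)
  for (b in seq_len(B)) x[((b - 1) * n + 1):(b * n), 1] <- as.vector(images[[b]])
  x
}

#' Train a segmentation model on labeled scans
#'
#' Adam on mean per-image Dice loss (optionally plus binary cross-entropy).
#' Deterministic given `seed`: shuffling, initialization and all updates are
#' driven by seeds derived from it.
#'
#' @param dataset List of `labeled_scan`s with tumor masks.
#' @param config A [segnet_config()] (its seed is overridden by `seed`).
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param seed Master seed.
#' @param bce_weight Weight of an optional added binary cross-entropy term.
#' @return List: `model` (trained `seg_model`), `loss_trace` (mean loss per
#'   epoch), `step_losses`.
#' @export
train_segmenter <- function(dataset, config = segnet_config(), epochs = 5,
                            lr = 1e-3, batch_size = 8, seed = 1L,
                            bce_weight = 0) {
  if (length(dataset) == 0) stop("empty dataset")
  config$seed <- derive_seed(seed, "init")
  model <- build_segnet(config)
  fp <- flatten_params(model$layers)
  opt <- adam_init(length(fp$values))
  n <- length(dataset)
  traces <- numeric(epochs)
  step_losses <- numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, "epoch", ep), sample(n))
    ep_losses <- numeric(0)
    for (start in seq(1, n, batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      imgs <- lapply(dataset[idx], `[[`, "image")
      x <- stack_images(imgs)
      B <- length(idx)
      fw <- segnet_forward(model, x, B, train = TRUE)
      model <- fw$model
      npix <- config$input_size^2
      loss <- 0
      dy <- matrix(0, nrow(fw$y), 1)
      for (b in seq_len(B)) {
        rows <- ((b - 1) * npix + 1):(b * npix)
        p <- fw$y[rows, 1]
        gmask <- as.numeric(dataset[[idx[b]]]$tumor_mask)
        loss_b <- dice_loss(p, gmask)
        grad_b <- dice_loss_grad(p, gmask)
        if (bce_weight > 0) {
          pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
          loss_b <- loss_b - bce_weight *
            mean(gmask * log(pc) + (1 - gmask) * log(1 - pc))
          grad_b <- grad_b +
            bce_weight * (pc - gmask) / (pc * (1 - pc)) / length(pc)
        }
        loss <- loss + loss_b / B
        dy[rows, 1] <- grad_b / B
      }
      if (!is.finite(loss))
        stop("non-finite loss at epoch ", ep, ", step ", start)
      bw <- segnet_backward(model, fw$caches, dy)
      gflat <- flatten_params(bw$grads)$values
      st <- adam_step(opt, fp$values, gflat, lr)
      opt <- st$state
      fp$values <- st$params
      model$layers <- unflatten_params(model$layers, fp$values)
      ep_losses <- c(ep_losses, loss)
    }
    traces[ep] <- mean(ep_losses)
    step_losses <- c(step_losses, ep_losses)
  }
  list(model = model, loss_trace = traces, step_losses = step_losses)
}

#' Segment one image
#'
#' @param model A trained `seg_model`.
#' @param image Grayscale matrix; resized (bilinear, with a warning) if it
#'   does not match the configured input size.
#' @param threshold Probability threshold; the mask is `prob >= threshold`.
#' @return List: `mask` (logical), `prob` (probability map in `[0, 1]`).
#' @export
segment <- function(model, image, threshold = 0.5) {
  sz <- model$config$input_size
  if (!all(dim(image) == c(sz, sz))) {
    warning("resizing image to the configured input size ", sz, "x", sz)
    r <- matrix(seq(1, nrow(image), length.out = sz), sz, sz)
    c <- matrix(seq(1, ncol(image), length.out = sz), sz, sz, byrow = TRUE)
    image <- matrix(bilinear_sample(image, as.vector(r), as.vector(c)), sz, sz)
  }
  fw <- segnet_forward(model, matrix(as.vector(image), ncol = 1), 1L,
                       train = FALSE)
  prob <- matrix(fw$y[, 1], sz, sz)
  list(mask = prob >= threshold, prob = prob)
}
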