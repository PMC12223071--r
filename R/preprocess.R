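# Preprocessing chain: morphological skull stripping, Perona-Malik
# anisotropic diffusion, min-max normalization, mutual-information rigid
# registration, and the SSIM/PSNR quality gate for synthetic images.

#' Disk-shaped structuring element
#'
#' @param radius Disk radius in pixels.
#' @return A `structuring_element`: a logical footprint matrix (odd side,
#'   symmetric about its center) plus offset coordinates.
#' @export
disk_se <- function(radius = 1) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  inside <- sqrt(g$dr^2 + g$dc^2) <= radius + 1e-9
  fp <- matrix(inside, 2 * r + 1, 2 * r + 1)
  if (!any(fp)) stop("empty footprint")
  structure(list(shape = "disk", radius = radius, footprint = fp,
                 offsets = as.matrix(g[inside, , drop = FALSE])),
            class = "structuring_element")
}

# shift a logical matrix by (dr, dc), padding with `fill`
shift_mask <- function(m, dr, dc, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Binary erosion
#'
#' Set-definition erosion: a pixel survives iff the structuring element
#' translated to it fits entirely inside the foreground. Pixels outside the
#' image count as background, so foreground touching the border is eroded.
#'
#' @param mask Binary matrix.
#' @param se A [disk_se()] (or any `structuring_element`).
#' @return Logical matrix, a subset of `mask`.
#' @export
erode <- function(mask, se) {
  stopifnot_binary(mask)
  mask <- as_binary(mask)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(se$offsets)))
    out <- out & shift_mask(mask, -se$offsets[i, 1], -se$offsets[i, 2], FALSE)
  out
}

#' Binary dilation
#'
#' A pixel is set iff the (symmetric) structuring element placed at it hits
#' the foreground anywhere.
#'
#' @inheritParams erode
#' @return Logical matrix, a superset of `mask` (when the footprint contains
#'   the origin).
#' @export
dilate <- function(mask, se) {
  stopifnot_binary(mask)
  mask <- as_binary(mask)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(se$offsets)))
    out <- out | shift_mask(mask, se$offsets[i, 1], se$offsets[i, 2], FALSE)
  out
}

#' Morphological skull stripping
#'
#' Pipeline: Otsu threshold, erosion (detaches the skull ring across the CSF
#' gap), keep the largest connected component, dilation (restores the eroded
#' margin), hole filling. Returns a single connected brain mask.
#'
#' @param image Grayscale matrix in `[0, 1]`.
#' @param radius Disk radius for the erosion/dilation pair.
#' @return Logical brain mask; empty (with a warning) for blank images.
#' @export
skull_strip <- function(image, radius = 2) {
  if (max(image) - min(image) < 1e-12) {
    warning("blank image: returning empty mask")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  thr <- EBImage::otsu(EBImage::Image(image), range = c(0, 1))
  fg <- image > thr
  se <- disk_se(radius)
  er <- erode(fg, se)
  if (!any(er)) {
    warning("erosion removed all foreground: returning empty mask")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  lab <- EBImage::bwlabel(EBImage::Image(er * 1))
  tab <- tabulate(as.integer(lab[lab > 0]))
  keep <- matrix(as.integer(lab) == which.max(tab), nrow(image), ncol(image))
  out <- dilate(keep, se)
  out <- as_binary(matrix(as.integer(
    EBImage::fillHull(EBImage::Image(out * 1))) > 0, nrow(image), ncol(image)))
  out
}

#' Diffusion parameters
#'
#' @param n_iter Number of explicit time steps.
#' @param kappa Edge threshold (conduction scale); gradients well above
#'   `kappa` are preserved, below are smoothed.
#' @param lam Step size; must lie in `(0, 0.25]` for 4-neighbour stability.
#' @param conduction `"exponential"` (`exp(-(x/kappa)^2)`) or `"rational"`
#'   (`1/(1+(x/kappa)^2)`).
#' @return A `diffusion_params` object.
#' @export
diffusion_params <- function(n_iter = 10, kappa = 0.1, lam = 0.2,
                             conduction = c("exponential", "rational")) {
  if (lam <= 0 || lam > 0.25) stop("lam must be in (0, 0.25]")
  if (kappa <= 0) stop("kappa must be > 0")
  if (n_iter < 0) stop("n_iter must be >= 0")
  structure(list(n_iter = as.integer(n_iter), kappa = kappa, lam = lam,
                 conduction = match.arg(conduction)),
            class = "diffusion_params")
}

#' Perona-Malik anisotropic diffusion
#'
#' Explicit 4-neighbour discretization of `dI/dt = div(c(|grad I|) grad I)`
#' with Neumann (replicate) boundaries. Each edge's conduction coefficient is
#' computed from the intensity difference across that edge, so the scheme is
#' conservative: the global mean is preserved every iteration.
#'
#' @param image Grayscale matrix.
#' @param params A [diffusion_params()].
#' @return Diffused image, same shape.
#' @export
anisotropic_diffusion <- function(image, params = diffusion_params()) {
  stopifnot(inherits(params, "diffusion_params"))
  g <- if (params$conduction == "exponential")
    function(d) exp(-(d / params$kappa)^2)
  else function(d) 1 / (1 + (d / params$kappa)^2)
  I <- image
  h <- nrow(I); w <- ncol(I)
  for (it in seq_len(params$n_iter)) {
    dN <- rbind(I[1, , drop = FALSE], I[-h, , drop = FALSE]) - I
    dS <- rbind(I[-1, , drop = FALSE], I[h, , drop = FALSE]) - I
    dW <- cbind(I[, 1, drop = FALSE], I[, -w, drop = FALSE]) - I
    dE <- cbind(I[, -1, drop = FALSE], I[, w, drop = FALSE]) - I
    I <- I + params$lam * (g(abs(dN)) * dN + g(abs(dS)) * dS +
                           g(abs(dW)) * dW + g(abs(dE)) * dE)
  }
  I
}

#' Min-max normalization
#'
#' Affine rescaling `(v - min) / (max - min) * (new_max - new_min) + new_min`;
#' preserves rank order and attains the new bounds exactly.
#'
#' @param x Numeric vector, matrix or array.
#' @param new_min,new_max Target range.
#' @param const_fill Value to return (uniformly) for constant input; if `NULL`
#'   (default) constant input is an error.
#' @return Same shape as `x`.
#' @export
#' @examples
#' minmax_normalize(c(2, 4, 10)) # 0, 0.25, 1
minmax_normalize <- function(x, new_min = 0, new_max = 1, const_fill = NULL) {
  lo <- min(x); hi <- max(x)
  if (hi - lo < .Machine$double.eps * max(1, abs(hi))) {
    if (is.null(const_fill))
      stop("constant input: range is degenerate (set const_fill to allow)")
    x[] <- const_fill
    return(x)
  }
  (x - lo) / (hi - lo) * (new_max - new_min) + new_min
}

#' Mutual information between two images (bits)
#'
#' Each image is binned over its own intensity range into `bins` equal-width
#' bins; MI = H(a) + H(b) - H(a, b) from the joint histogram, base-2 logs.
#'
#' @param a,b Same-shape numeric matrices.
#' @param bins Number of histogram bins (>= 2).
#' @return Non-negative scalar, bits.
#' @export
mutual_information <- function(a, b, bins = 32) {
  if (!all(dim(a) == dim(b))) stop("images must have the same shape")
  if (bins < 2) stop("bins must be >= 2")
  qa <- quantize_minmax(a, bins)
  qb <- quantize_minmax(b, bins)
  joint <- tabulate((qa - 1L) * bins + qb, nbins = bins * bins)
  p <- joint / sum(joint)
  pa <- rowSums(matrix(p, bins, bins, byrow = TRUE)) # over qa
  pb <- colSums(matrix(p, bins, bins, byrow = TRUE))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  max(0, ent(pa) + ent(pb) - ent(p))
}

# min-max quantization to integer levels 1..n (constant input -> all 1)
quantize_minmax <- function(x, n) {
  lo <- min(x); hi <- max(x)
  if (hi - lo < .Machine$double.eps * max(1, abs(hi)))
    return(array(1L, dim(x) %||% length(x)))
  q <- pmin(as.integer(floor((x - lo) / (hi - lo) * n)) + 1L, n)
  array(q, dim(x) %||% length(x))
}

#' Rigid transform (shift + rotation about image center)
#'
#' @param dy,dx Row/column displacement of the moving image's content
#'   relative to the fixed image, pixels.
#' @param theta Rotation in degrees, in `(-180, 180]`.
#' @return A `rigid_transform`.
#' @export
rigid_transform <- function(dy = 0, dx = 0, theta = 0) {
  if (!all(is.finite(c(dy, dx, theta)))) stop("transform must be finite")
  if (theta <= -180 || theta > 180) stop("theta must be in (-180, 180]")
  structure(list(dy = dy, dx = dx, theta = theta), class = "rigid_transform")
}

# bilinear sampling with replicate edges at fractional (r, c) coordinates
bilinear_sample <- function(image, r, c) {
  h <- nrow(image); w <- ncol(image)
  r <- pmin(pmax(r, 1), h); c <- pmin(pmax(c, 1), w)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- pmin(r0 + 1, h); c1 <- pmin(c0 + 1, w)
  fr <- r - r0; fc <- c - c0
  at <- function(rr, cc) image[cbind(rr, cc)]
  (1 - fr) * (1 - fc) * at(r0, c0) + (1 - fr) * fc * at(r0, c1) +
    fr * (1 - fc) * at(r1, c0) + fr * fc * at(r1, c1)
}

#' Resample an image under an (inverse-applied) rigid transform
#'
#' Produces the moving image re-aligned so that content displaced by
#' `(dy, dx)` and rotated by `theta` is brought back onto the fixed frame.
#'
#' @param image Moving image.
#' @param tf A [rigid_transform()] describing the moving image's displacement.
#' @return Resampled image (bilinear, replicate edges).
#' @export
apply_rigid <- function(image, tf) {
  h <- nrow(image); w <- ncol(image)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- tf$theta * pi / 180
  r <- matrix(seq_len(h), h, w)
  c <- matrix(seq_len(w), h, w, byrow = TRUE)
  # target pixel (r, c) in the fixed frame came from the moving image at the
  # forward-transformed location: rotate about center then shift
  rr <- r - cy; cc <- c - cx
  rs <- cos(th) * rr - sin(th) * cc + cy + tf$dy
  cs <- sin(th) * rr + cos(th) * cc + cx + tf$dx
  matrix(bilinear_sample(image, as.vector(rs), as.vector(cs)), h, w)
}

#' Rigid registration by mutual-information maximization
#'
#' Deterministic search: exhaustive integer-shift grid at zero rotation,
#' golden-section refinement over the rotation angle at the best shift, then
#' a half-pixel local shift refinement at the best angle.
#'
#' @param moving,fixed Same-shape images.
#' @param max_shift Half-width of the integer shift grid, pixels.
#' @param max_angle Half-width of the angle search, degrees (0 disables
#'   rotation search).
#' @param bins Histogram bins for the MI metric.
#' @return List with `transform` (the estimated displacement of `moving`
#'   relative to `fixed`), `registered` (moving resampled onto the fixed
#'   frame) and `mi` (the attained mutual information, bits).
#' @export
register_rigid <- function(moving, fixed, max_shift = 8, max_angle = 10,
                           bins = 32) {
  if (!all(dim(moving) == dim(fixed))) stop("images must have the same shape")
  if (max_shift < 0) stop("empty search range")
  score <- function(dy, dx, th)
    mutual_information(apply_rigid(moving, rigid_transform(dy, dx, th)),
                       fixed, bins)
  best <- list(dy = 0, dx = 0, th = 0, mi = score(0, 0, 0))
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    mi <- score(dy, dx, 0)
    if (mi > best$mi) best <- list(dy = dy, dx = dx, th = 0, mi = mi)
  }
  if (max_angle > 0) {
    opt <- stats::optimize(function(th) -score(best$dy, best$dx, th),
                           c(-max_angle, max_angle), tol = 0.05)
    if (-opt$objective > best$mi) {
      best$th <- opt$minimum
      best$mi <- -opt$objective
    }
  }
  for (ddy in seq(-1, 1, 0.5)) for (ddx in seq(-1, 1, 0.5)) {
    mi <- score(best$dy + ddy, best$dx + ddx, best$th)
    if (mi > best$mi)
      best <- list(dy = best$dy + ddy, dx = best$dx + ddx, th = best$th,
                   mi = mi)
  }
  tf <- rigid_transform(best$dy, best$dx, best$th)
  list(transform = tf, registered = apply_rigid(moving, tf), mi = best$mi)
}

#' Separable Gaussian blur with replicate padding
#'
#' @param image Numeric matrix.
#' @param sigma Standard deviation in pixels.
#' @return Blurred image.
#' @export
gaussian_blur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  h <- nrow(image); w <- ncol(image)
  pad_r <- image[c(rep(1, r), 1:h, rep(h, r)), , drop = FALSE]
  tmp <- apply(pad_r, 2, function(col) stats::filter(col, k)[(r + 1):(r + h)])
  pad_c <- tmp[, c(rep(1, r), 1:w, rep(w, r)), drop = FALSE]
  out <- t(apply(pad_c, 1, function(row)
    stats::filter(row, k)[(r + 1):(r + w)]))
  matrix(out, h, w)
}

#' Structural similarity index (mean SSIM, Gaussian window)
#'
#' @param a,b Same-shape images on a unit dynamic range.
#' @param sigma Gaussian window standard deviation (classic 1.5).
#' @param K1,K2 Stabilization constants.
#' @return Scalar mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(a, b, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  if (!all(dim(a) == dim(b))) stop("images must have the same shape")
  C1 <- (K1)^2; C2 <- (K2)^2
  mu_a <- gaussian_blur(a, sigma); mu_b <- gaussian_blur(b, sigma)
  va <- gaussian_blur(a * a, sigma) - mu_a^2
  vb <- gaussian_blur(b * b, sigma) - mu_b^2
  cab <- gaussian_blur(a * b, sigma) - mu_a * mu_b
  m <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
       ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(m)
}

#' Peak signal-to-noise ratio (dB, peak = 1)
#'
#' @param a,b Same-shape images on a unit dynamic range.
#' @return `20 * log10(1 / RMSE)`; `Inf` for identical images.
#' @export
psnr <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("images must have the same shape")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(1 / mse)
}

#' SSIM/PSNR quality gate for synthetic images
#'
#' @param candidate,reference Same-shape unit-range images.
#' @param ssim_min,psnr_min Acceptance thresholds.
#' @return List with `accept`, `ssim`, `psnr`.
#' @export
quality_gate <- function(candidate, reference, ssim_min = 0.75,
                         psnr_min = 22) {
  if (max(reference) - min(reference) < 1e-12)
    stop("reference has zero dynamic range: SSIM undefined")
  s <- ssim(candidate, reference)
  p <- psnr(candidate, reference)
  list(accept = (s >= ssim_min) && (p >= psnr_min), ssim = s, psnr = p)
}
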