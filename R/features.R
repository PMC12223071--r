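# Handcrafted texture / first-order features over a region of interest, deep
# pooled features, and their fusion into one named feature vector per scan.

#' Gray-level co-occurrence matrix
#'
#' Intensities inside the ROI are min-max quantized to `levels` gray levels;
#' pair counts are accumulated for the given offset (both pixels must lie in
#' the ROI), optionally plus the reversed offset (symmetric accumulation),
#' then normalized to sum 1.
#'
#' @param image Numeric matrix.
#' @param roi Logical ROI mask (default: whole image).
#' @param levels Number of gray levels `N` (>= 2).
#' @param offset Integer `(dr, dc)` displacement between pair members.
#' @param symmetric Also count the reversed offset?
#' @return A `glcm` object: `P` (`levels x levels`, sums to 1), plus
#'   quantization and offset metadata.
#' @export
#' @examples
#' g <- compute_glcm(matrix(c(0, 1, 0, 1), 2, 2), levels = 2,
#'                   offset = c(0, 1), symmetric = FALSE)
#' g$P
compute_glcm <- function(image, roi = NULL, levels = 8, offset = c(0, 1),
                         symmetric = TRUE) {
  if (is.null(roi)) roi <- matrix(TRUE, nrow(image), ncol(image))
  stopifnot_binary(roi, "roi")
  roi <- as_binary(roi)
  if (!any(roi)) stop("roi is empty")
  if (levels < 2) stop("levels must be >= 2")
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  q[roi] <- quantize_minmax(image[roi], levels)
  count_pairs <- function(dr, dc) {
    h <- nrow(q); w <- ncol(q)
    r1 <- seq_len(h - abs(dr)); c1 <- seq_len(w - abs(dc))
    if (dr < 0) r1 <- r1 + abs(dr)
    if (dc < 0) c1 <- c1 + abs(dc)
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return(matrix(0, levels, levels))
    matrix(tabulate((a[ok] - 1L) * levels + b[ok], nbins = levels^2),
           levels, levels, byrow = TRUE)
  }
  P <- count_pairs(offset[1], offset[2])
  if (symmetric) P <- P + count_pairs(-offset[1], -offset[2])
  tot <- sum(P)
  if (tot < 1) stop("roi has fewer than one valid pixel pair at this offset")
  structure(list(P = P / tot, levels = as.integer(levels),
                 offset = as.integer(offset), symmetric = symmetric),
            class = "glcm")
}

check_glcm <- function(g) {
  stopifnot(inherits(g, "glcm"), all(g$P >= 0),
            abs(sum(g$P) - 1) < 1e-8)
  invisible(g)
}

glcm_ij <- function(g) {
  n <- g$levels
  list(i = matrix(0:(n - 1), n, n), j = matrix(0:(n - 1), n, n, byrow = TRUE))
}

#' GLCM contrast: sum of P(i,j) (i-j)^2
#' @param g A [compute_glcm()] result.
#' @return Non-negative scalar.
#' @export
glcm_contrast <- function(g) {
  check_glcm(g)
  ij <- glcm_ij(g)
  sum(g$P * (ij$i - ij$j)^2)
}

#' GLCM energy (uniformity): sum of squared entries
#' @inheritParams glcm_contrast
#' @return Scalar in `(0, 1]`.
#' @export
glcm_energy <- function(g) {
  check_glcm(g)
  sum(g$P^2)
}

#' GLCM homogeneity: sum of P(i,j) / (1 + |i-j|)
#' @inheritParams glcm_contrast
#' @return Scalar in `(0, 1]`.
#' @export
glcm_homogeneity <- function(g) {
  check_glcm(g)
  ij <- glcm_ij(g)
  sum(g$P / (1 + abs(ij$i - ij$j)))
}

#' GLCM correlation (standard definition)
#' @inheritParams glcm_contrast
#' @return Scalar in `[-1, 1]`; errors when a marginal variance is zero.
#' @export
glcm_correlation <- function(g) {
  check_glcm(g)
  n <- g$levels
  lev <- 0:(n - 1)
  pi_ <- rowSums(g$P); pj <- colSums(g$P)
  mi <- sum(lev * pi_); mj <- sum(lev * pj)
  si <- sqrt(sum((lev - mi)^2 * pi_)); sj <- sqrt(sum((lev - mj)^2 * pj))
  if (si < 1e-12 || sj < 1e-12)
    stop("zero marginal variance: correlation undefined")
  ij <- glcm_ij(g)
  sum((ij$i - mi) * (ij$j - mj) * g$P) / (si * sj)
}

#' First-order intensity statistics over an ROI
#'
#' Population formulas (divide by the pixel count, not count - 1); kurtosis
#' is non-excess, so a Gaussian gives 3.
#'
#' @param image Numeric matrix.
#' @param roi Logical ROI mask (default whole image).
#' @return List with `mean`, `sd`, `skewness`, `kurtosis`, `n_pixels`.
#'   Skewness/kurtosis error on zero spread.
#' @export
first_order_stats <- function(image, roi = NULL) {
  if (is.null(roi)) roi <- matrix(TRUE, nrow(image), ncol(image))
  stopifnot_binary(roi, "roi")
  v <- image[as_binary(roi)]
  n <- length(v)
  if (n < 1) stop("roi is empty")
  mu <- sum(v) / n
  sd_ <- sqrt(sum((v - mu)^2) / n)
  if (sd_ < 1e-300) stop("zero intensity spread: skewness/kurtosis undefined")
  z <- (v - mu) / sd_
  list(mean = mu, sd = sd_, skewness = sum(z^3) / n,
       kurtosis = sum(z^4) / n, n_pixels = n)
}

#' Global average pooling over a channel stack
#'
#' @param feature_maps `H x W x C` array (or a matrix = one channel).
#' @return Numeric vector of length `C`: per-channel spatial means.
#' @export
gap_pool <- function(feature_maps) {
  if (is.matrix(feature_maps))
    feature_maps <- array(feature_maps, c(dim(feature_maps), 1))
  d <- dim(feature_maps)
  if (length(d) != 3 || any(d < 1)) stop("expected a nonempty H x W x C stack")
  apply(feature_maps, 3, mean)
}

#' Fuse deep and handcrafted features
#'
#' Weighted concatenation `[alpha * deep, beta * handcrafted]`. When both
#' blocks have equal length a weighted elementwise sum is available instead.
#'
#' @param deep,handcrafted Named or unnamed numeric vectors.
#' @param alpha,beta Non-negative block weights (not both zero).
#' @param method `"concat"` (default) or `"sum"` (equal lengths only).
#' @return A `feature_vector`: `values`, `names` (provenance-prefixed),
#'   `provenance`.
#' @export
fuse_features <- function(deep, handcrafted, alpha = 1, beta = 1,
                          method = c("concat", "sum")) {
  method <- match.arg(method)
  if (length(deep) == 0 || length(handcrafted) == 0) stop("empty inputs")
  if (alpha < 0 || beta < 0 || (alpha == 0 && beta == 0))
    stop("alpha, beta must be >= 0 and not both zero")
  dn <- names(deep) %||% paste0("d", seq_along(deep))
  hn <- names(handcrafted) %||% paste0("h", seq_along(handcrafted))
  if (method == "sum") {
    if (length(deep) != length(handcrafted))
      stop("weighted sum requires equal-length blocks")
    values <- alpha * as.numeric(deep) + beta * as.numeric(handcrafted)
    nms <- paste0("fused.", dn)
  } else {
    values <- c(alpha * as.numeric(deep), beta * as.numeric(handcrafted))
    nms <- c(paste0("deep.", dn), paste0("hand.", hn))
  }
  if (!all(is.finite(values))) stop("non-finite feature values")
  structure(list(values = values, names = nms, provenance = "fused"),
            class = "feature_vector")
}

#' Handcrafted feature block for one scan
#'
#' GLCM contrast/energy/homogeneity/correlation averaged over the configured
#' offsets, plus first-order statistics, computed over an ROI (tumor mask
#' when nonempty, else brain mask, else whole image).
#'
#' @param scan A `labeled_scan`.
#' @param levels GLCM gray levels.
#' @param offsets List of `(dr, dc)` offsets to average over.
#' @return Named numeric vector of 9 features.
#' @export
handcrafted_features <- function(scan, levels = 8,
                                 offsets = list(c(0, 1), c(1, 0))) {
  roi <- if (any(scan$tumor_mask)) scan$tumor_mask
         else if (any(scan$brain_mask)) scan$brain_mask
         else matrix(TRUE, nrow(scan$image), ncol(scan$image))
  tex <- vapply(offsets, function(off) {
    g <- compute_glcm(scan$image, roi, levels = levels, offset = off)
    corr <- tryCatch(glcm_correlation(g), error = function(e) 0)
    c(glcm_contrast(g), glcm_energy(g), glcm_homogeneity(g), corr)
  }, numeric(4))
  tex <- rowMeans(tex)
  names(tex) <- c("contrast", "energy", "homogeneity", "correlation")
  fo <- tryCatch(first_order_stats(scan$image, roi),
                 error = function(e) list(mean = mean(scan$image[roi]), sd = 0,
                                          skewness = 0, kurtosis = 0,
                                          n_pixels = sum(roi)))
  c(tex, mean = fo$mean, sd = fo$sd, skew = fo$skewness, kurt = fo$kurtosis,
    roi_frac = fo$n_pixels / length(scan$image))
}
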