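# Synthetic CT-like brain phantoms: an oval brain inside a bright skull ring,
# optionally carrying a bright irregular tumor blob, plus a deterministic
# pseudo-modality remap standing in for a learned CT->MRI translation channel.
# All geometry uses (row, col) coordinates, 1-based in R, masks are logical.

TUMOR_TYPES <- c("glioma-like", "meningioma-like", "pituitary-like")

# geometric presets per tumor "type": a relative size multiplier, an axis
# ratio (1 = round), and a boundary roughness amplitude. The type labels only
# drive client heterogeneity; they are not biology.
type_presets <- function(type) {
  switch(type,
    "glioma-like"     = list(size = 1.00, ecc = 0.70, rough = 0.30),
    "meningioma-like" = list(size = 0.80, ecc = 1.00, rough = 0.10),
    "pituitary-like"  = list(size = 0.55, ecc = 0.85, rough = 0.20),
    stop("unknown tumor type: ", type))
}

#' Specification of one synthetic brain phantom
#'
#' @param height,width Image size in pixels.
#' @param brain_axes Semi-axes (rows, cols) of the brain ellipse, pixels.
#' @param skull_thickness Thickness of the bright skull ring, pixels.
#' @param csf_gap Width of the dark cerebrospinal-fluid gap (at background
#'   intensity) separating brain from skull, pixels.
#' @param tumor_present Should a tumor blob be drawn?
#' @param tumor_type One of `"glioma-like"`, `"meningioma-like"`,
#'   `"pituitary-like"`; maps to (size, axis-ratio, boundary-roughness)
#'   presets.
#' @param tumor_radius Nominal tumor radius in pixels (before the type's size
#'   multiplier).
#' @param intensity_levels Named numeric vector with entries `background`,
#'   `brain`, `tumor`, `skull`, each in `[0, 1]`, strictly ordered
#'   background < brain < tumor < skull.
#' @param noise_sigma Standard deviation of additive Gaussian intensity noise.
#' @param seed Integer seed; the phantom is a pure function of its spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 64L, width = 64L,
                         brain_axes = c(20, 24),
                         skull_thickness = 3,
                         csf_gap = 2,
                         tumor_present = TRUE,
                         tumor_type = "glioma-like",
                         tumor_radius = 6,
                         intensity_levels = c(background = 0.05, brain = 0.45,
                                              tumor = 0.75, skull = 0.95),
                         noise_sigma = 0.03,
                         seed = 1L) {
  lv <- intensity_levels[c("background", "brain", "tumor", "skull")]
  if (anyNA(lv)) stop("intensity_levels needs background/brain/tumor/skull")
  if (!(lv["background"] < lv["brain"] && lv["brain"] < lv["tumor"] &&
        lv["tumor"] < lv["skull"]))
    stop("intensity means must be ordered background < brain < tumor < skull")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (tumor_present) tumor_type <- match.arg(tumor_type, TUMOR_TYPES)
  if (length(brain_axes) != 2 || any(brain_axes <= 0))
    stop("brain_axes must be two positive semi-axes")
  structure(list(height = as.integer(height), width = as.integer(width),
                 brain_axes = as.numeric(brain_axes),
                 skull_thickness = as.numeric(skull_thickness),
                 csf_gap = as.numeric(csf_gap),
                 tumor_present = isTRUE(tumor_present),
                 tumor_type = if (tumor_present) tumor_type else NA_character_,
                 tumor_radius = as.numeric(tumor_radius),
                 intensity_levels = lv, noise_sigma = as.numeric(noise_sigma),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

new_labeled_scan <- function(image, brain_mask, tumor_mask, label, tumor_type,
                             modality = "ct", client_id = NA_character_,
                             id = NA_character_, seed = NA_integer_) {
  structure(list(image = image, brain_mask = brain_mask,
                 tumor_mask = tumor_mask, label = label,
                 tumor_type = tumor_type, client_id = client_id,
                 modality = modality, id = id, seed = seed),
            class = "labeled_scan")
}

#' @export
print.labeled_scan <- function(x, ...) {
  cat(sprintf("<labeled_scan %s> %dx%d %s label=%s type=%s client=%s\n",
              x$id %||% "?", nrow(x$image), ncol(x$image), x$modality,
              x$label, x$tumor_type, x$client_id))
  invisible(x)
}

ellipse_mask <- function(h, w, center, axes) {
  r <- matrix(seq_len(h), h, w)
  c <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((r - center[1]) / axes[1])^2 + ((c - center[2]) / axes[2])^2 <= 1
}

# Star-shaped blob: radius R(theta) = R * (1 + rough * s(theta)) with s a
# smooth zero-mean harmonic series. Star-convexity keeps the pixelized blob a
# single connected component.
blob_mask <- function(h, w, center, radius, ecc, rough) {
  nharm <- 4L
  amp <- stats::runif(nharm, -1, 1)
  amp <- amp / max(1, sum(abs(amp)))       # |s(theta)| <= 1
  phase <- stats::runif(nharm, 0, 2 * pi)
  ax_r <- radius * sqrt(ecc)               # area ~ pi * radius^2 for any ecc
  ax_c <- radius / sqrt(ecc)
  r <- matrix(seq_len(h), h, w) - center[1]
  c <- matrix(seq_len(w), h, w, byrow = TRUE) - center[2]
  u <- r / ax_r
  v <- c / ax_c
  theta <- atan2(v, u)
  s <- 0
  for (k in seq_len(nharm)) s <- s + amp[k] * sin((k + 1) * theta + phase[k])
  sqrt(u^2 + v^2) <= (1 + rough * s)
}

#' Generate one labeled brain phantom
#'
#' Draws background, brain ellipse, skull ring and (optionally) a tumor blob
#' at the spec's intensity levels, then adds Gaussian noise and clips to
#' `[0, 1]`. Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A `labeled_scan` with fields `image`, `brain_mask`, `tumor_mask`,
#'   `label` (`"tumor"`/`"no-tumor"`), `tumor_type`, `modality` (`"ct"`).
#' @export
#' @examples
#' scan <- generate_phantom(phantom_spec(seed = 7))
#' table(scan$tumor_mask)
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    center <- c((h + 1) / 2, (w + 1) / 2)
    lv <- spec$intensity_levels
    brain <- ellipse_mask(h, w, center, spec$brain_axes)
    inner <- ellipse_mask(h, w, center, spec$brain_axes + spec$csf_gap)
    outer <- ellipse_mask(h, w, center,
                          spec$brain_axes + spec$csf_gap + spec$skull_thickness)
    skull <- outer & !inner # CSF gap between brain and skull stays background
    img <- matrix(lv[["background"]], h, w)
    img[brain] <- lv[["brain"]]
    img[skull] <- lv[["skull"]]
    tumor <- matrix(FALSE, h, w)
    if (spec$tumor_present) {
      ps <- type_presets(spec$tumor_type)
      R <- spec$tumor_radius * ps$size
      Rmax <- (R / sqrt(ps$ecc)) * (1 + ps$rough)  # widest possible extent
      if (Rmax >= min(spec$brain_axes))
        stop("geometry error: tumor_radius too large to fit inside brain")
      ok <- FALSE
      for (try in 1:100) {
        # candidate center inside a shrunken brain ellipse so the whole blob
        # stays strictly interior
        shrink <- 1 - Rmax / min(spec$brain_axes)
        cand <- center + c(stats::runif(1, -1, 1) * spec$brain_axes[1],
                           stats::runif(1, -1, 1) * spec$brain_axes[2]) * shrink
        e <- ((cand[1] - center[1]) / (spec$brain_axes[1] - Rmax))^2 +
             ((cand[2] - center[2]) / (spec$brain_axes[2] - Rmax))^2
        if (e <= 1) { ok <- TRUE; break }
      }
      if (!ok) stop("geometry error: could not place tumor inside brain")
      tumor <- blob_mask(h, w, cand, R, ps$ecc, ps$rough) & brain
      img[tumor] <- lv[["tumor"]]
    }
    if (spec$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
    img <- pmin(pmax(img, 0), 1)
    new_labeled_scan(img, brain, tumor,
                     label = if (any(tumor)) "tumor" else "no-tumor",
                     tumor_type = spec$tumor_type, seed = spec$seed)
  })
}

#' Generate a labeled phantom dataset
#'
#' Produces `n` scans of which exactly `round(n * tumor_fraction)` carry a
#' tumor. Per-scan seeds are derived from the master seed and the scan index,
#' so the dataset is reproducible independent of generation order.
#'
#' @param n Number of scans.
#' @param tumor_fraction Fraction of tumor-labeled scans in `[0, 1]`.
#' @param spec_template A [phantom_spec()] supplying geometry/intensity/noise
#'   defaults; `tumor_present`, `tumor_type` and `seed` are overridden per scan.
#' @param seed Master seed.
#' @param type_mix Named probabilities over tumor types used to draw each
#'   tumor scan's type.
#' @return List of `labeled_scan` objects with ids `"scan-0001"`, ...
#' @export
generate_dataset <- function(n, tumor_fraction = 0.5,
                             spec_template = phantom_spec(),
                             seed = 1L,
                             type_mix = c("glioma-like" = 1/3,
                                          "meningioma-like" = 1/3,
                                          "pituitary-like" = 1/3)) {
  if (n <= 0) stop("n must be positive")
  if (tumor_fraction < 0 || tumor_fraction > 1)
    stop("tumor_fraction must be in [0, 1]")
  n <- as.integer(n)
  n_tumor <- as.integer(round(n * tumor_fraction))
  is_tumor <- with_seed(derive_seed(seed, "labels"),
                        sample(rep(c(TRUE, FALSE), c(n_tumor, n - n_tumor))))
  types <- with_seed(derive_seed(seed, "types"),
                     sample(names(type_mix), n, replace = TRUE,
                            prob = as.numeric(type_mix)))
  lapply(seq_len(n), function(i) {
    sp <- spec_template
    sp$tumor_present <- is_tumor[i]
    sp$tumor_type <- if (is_tumor[i]) types[i] else NA_character_
    sp$seed <- derive_seed(seed, "scan", i)
    scan <- generate_phantom(sp)
    scan$id <- sprintf("scan-%04d", i)
    scan
  })
}

#' Derive a pseudo-modality scan by monotone intensity remapping
#'
#' Applies a strictly monotone intensity lookup (linear interpolation between
#' equally spaced nodes on `[0, 1]`) followed by optional Gaussian blur. This
#' yields a distinct-but-aligned second imaging domain; masks and labels are
#' untouched.
#'
#' @param scan A `labeled_scan` with `modality == "ct"`.
#' @param lookup Strictly monotone (increasing or decreasing) numeric vector
#'   of node values; default is a gamma-like brightening `v^0.6`.
#' @param blur_sigma Gaussian blur standard deviation in pixels (0 = none).
#' @return A `labeled_scan` with `modality == "pseudo-mri"`.
#' @export
make_pseudo_modality <- function(scan, lookup = seq(0, 1, length.out = 33)^0.6,
                                 blur_sigma = 0.7) {
  stopifnot(inherits(scan, "labeled_scan"))
  if (!identical(scan$modality, "ct"))
    stop("input scan must have modality 'ct'")
  d <- diff(lookup)
  if (!(all(d > 0) || all(d < 0)))
    stop("lookup must be strictly monotone")
  nodes <- seq(0, 1, length.out = length(lookup))
  img <- matrix(stats::approx(nodes, lookup, xout = as.vector(scan$image),
                              rule = 2)$y,
                nrow(scan$image), ncol(scan$image))
  if (blur_sigma > 0) img <- gaussian_blur(img, blur_sigma)
  out <- scan
  out$image <- pmin(pmax(img, 0), 1)
  out$modality <- "pseudo-mri"
  out$id <- if (is.na(scan$id)) NA_character_ else paste0(scan$id, "-pmri")
  out
}

#' Client profile for federated partitioning
#'
#' @param client_id Client identifier.
#' @param n_ct,n_pseudo Requested CT and pseudo-modality sample counts.
#' @param type_mix Named proportions over tumor types (must sum to 1).
#' @param distribution_kind `"iid"`, `"non-iid"` or `"skewed"` (metadata).
#' @return A `client_profile`.
#' @export
client_profile <- function(client_id, n_ct, n_pseudo = 0,
                           type_mix = c("glioma-like" = 1/3,
                                        "meningioma-like" = 1/3,
                                        "pituitary-like" = 1/3),
                           distribution_kind = c("iid", "non-iid", "skewed")) {
  if (abs(sum(type_mix) - 1) > 1e-8) stop("type_mix must sum to 1")
  if (n_ct < 0 || n_pseudo < 0) stop("counts must be >= 0")
  structure(list(client_id = as.character(client_id),
                 n_ct = as.integer(n_ct), n_pseudo = as.integer(n_pseudo),
                 type_mix = type_mix,
                 distribution_kind = match.arg(distribution_kind)),
            class = "client_profile")
}

#' Five heterogeneous hospital profiles
#'
#' The default federated cohort: five clients mixing majority-glioma,
#' mixed meningioma/pituitary, single-type skewed, balanced IID, and
#' pituitary-dominated sites, with unequal sample counts
#' (400/420/410/430/440 CT plus 160/180/170/160/180 pseudo-modality).
#' `scale` shrinks every count (rounded) for desk-scale runs.
#'
#' @param scale Multiplier applied to all sample counts.
#' @return List of five [client_profile()]s.
#' @export
default_client_profiles <- function(scale = 1) {
  s <- function(n) max(1L, as.integer(round(n * scale)))
  list(
    client_profile("client-1", s(400), s(160),
                   c("glioma-like" = 0.7, "meningioma-like" = 0.3,
                     "pituitary-like" = 0), "non-iid"),
    client_profile("client-2", s(420), s(180),
                   c("glioma-like" = 0, "meningioma-like" = 0.5,
                     "pituitary-like" = 0.5), "non-iid"),
    client_profile("client-3", s(410), s(170),
                   c("glioma-like" = 1, "meningioma-like" = 0,
                     "pituitary-like" = 0), "skewed"),
    client_profile("client-4", s(430), s(160),
                   c("glioma-like" = 1/3, "meningioma-like" = 1/3,
                     "pituitary-like" = 1/3), "iid"),
    client_profile("client-5", s(440), s(180),
                   c("glioma-like" = 0.4, "meningioma-like" = 0,
                     "pituitary-like" = 0.6), "non-iid"))
}

# largest-remainder rounding of n into proportions p (sums exactly to n)
apportion <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Partition a dataset across federated clients
#'
#' Assigns disjoint samples to each client honoring its CT / pseudo-modality
#' counts and tumor-type mix (largest-remainder rounding keeps realized mixes
#' within one sample of the request). Tumor and non-tumor scans are allocated
#' at the dataset's global tumor fraction per client.
#'
#' @param dataset List of `labeled_scan`s.
#' @param profiles List of [client_profile()]s.
#' @param seed Seed for the (deterministic) shuffling of candidate pools.
#' @return Named list of per-client datasets; each scan is tagged with its
#'   `client_id`. Unassigned scans are dropped.
#' @export
partition_clients <- function(dataset, profiles, seed = 1L) {
  labels <- vapply(dataset, `[[`, "", "label")
  mods <- vapply(dataset, `[[`, "", "modality")
  types <- vapply(dataset, `[[`, "", "tumor_type")
  tumor_frac <- mean(labels == "tumor")
  # pools of indices keyed by modality x (type or "none"), shuffled once
  key <- paste(mods, ifelse(labels == "tumor", types, "none"))
  pools <- with_seed(derive_seed(seed, "partition"),
                     lapply(split(seq_along(dataset), key), sample))
  take <- function(k, n) {
    avail <- pools[[k]] %||% integer(0)
    if (length(avail) < n)
      stop(sprintf(
        "infeasible client mix: need %d of '%s' but only %d available",
        n, k, length(avail)))
    got <- avail[seq_len(n)]
    pools[[k]] <<- avail[-seq_len(n)]
    got
  }
  out <- list()
  for (pr in profiles) {
    idx <- integer(0)
    for (mod in c("ct", "pseudo-mri")) {
      n_mod <- if (mod == "ct") pr$n_ct else pr$n_pseudo
      if (n_mod == 0) next
      n_tum <- as.integer(round(n_mod * tumor_frac))
      per_type <- apportion(n_tum, as.numeric(pr$type_mix))
      for (j in seq_along(pr$type_mix))
        if (per_type[j] > 0)
          idx <- c(idx, take(paste(mod, names(pr$type_mix)[j]), per_type[j]))
      if (n_mod - n_tum > 0)
        idx <- c(idx, take(paste(mod, "none"), n_mod - n_tum))
    }
    client <- lapply(dataset[sort(idx)], function(s) {
      s$client_id <- pr$client_id
      s
    })
    out[[pr$client_id]] <- client
  }
  out
}

#' Write a dataset as PNG images plus a tab-separated manifest
#'
#' @param dataset List of `labeled_scan`s.
#' @param dir Output directory (created if needed).
#' @param write_masks Also write `*_tumor_mask.png` files?
#' @return Invisibly, the manifest data frame (path, label, type, client,
#'   modality, seed).
#' @export
write_dataset <- function(dataset, dir, write_masks = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dataset, function(s) {
    path <- file.path(dir, paste0(s$id %||% "scan", ".png"))
    png::writePNG(s$image, path)
    if (write_masks)
      png::writePNG(s$tumor_mask * 1,
                    file.path(dir, paste0(s$id %||% "scan", "_tumor_mask.png")))
    data.frame(path = path, label = s$label, tumor_type = s$tumor_type,
               client_id = s$client_id, modality = s$modality, seed = s$seed,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
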