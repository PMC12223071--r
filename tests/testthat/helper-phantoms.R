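# small-geometry fixtures used across the suite

spec32 <- function(seed = 1L, ...) {
  phantom_spec(height = 32, width = 32, brain_axes = c(10, 12),
               skull_thickness = 2, csf_gap = 1, tumor_radius = 4,
               seed = seed, ...)
}

# aggregate tumor-type composition of the five-hospital cohort, so that
# heterogeneous client mixes are satisfiable from a finite phantom pool
cohort_type_mix <- c("glioma-like" = 0.48, "meningioma-like" = 0.23,
                     "pituitary-like" = 0.29)

# feature-space world for federated experiments: phantoms + pseudo channel,
# fused standardized features, Table-12-style client partitions, CT-only
# held-out evaluation set
make_fl_world <- function(seed, n_ct = 260, n_pseudo = 100, n_eval = 60,
                          scale = 0.08) {
  ds <- generate_dataset(n_ct, 0.5, phantom_spec(), seed = seed,
                         type_mix = cohort_type_mix)
  idx <- phantomfed:::with_seed(derive_seed(seed, "ps"),
                                sample(length(ds), n_pseudo))
  ps <- lapply(ds[idx], make_pseudo_modality)
  all <- c(ds, ps)
  ft <- extract_feature_table(all, seed = 3)
  Xs <- scale(ft$X)
  Xs[!is.finite(Xs)] <- 0
  is_ct <- ft$meta$modality == "ct"
  ev <- phantomfed:::with_seed(derive_seed(seed, "ev"),
                               sample(which(is_ct), n_eval))
  pool <- setdiff(seq_along(all), ev)
  parts <- partition_clients(all[pool], default_client_profiles(scale),
                             seed = derive_seed(seed, "part"))
  ids <- vapply(all, `[[`, "", "id")
  clients <- lapply(parts, function(cl) {
    ix <- match(vapply(cl, `[[`, "", "id"), ids)
    list(X = Xs[ix, , drop = FALSE], y = ft$y[ix],
         client_id = cl[[1]]$client_id)
  })
  list(clients = clients,
       eval = list(X = Xs[ev, , drop = FALSE], y = ft$y[ev]))
}

# brute-force GLCM oracle: explicit pair enumeration
oracle_glcm_features <- function(img, levels, offset, symmetric = TRUE) {
  lo <- min(img); hi <- max(img)
  q <- if (hi - lo < 1e-300) matrix(1L, nrow(img), ncol(img))
  else pmin(as.integer(floor((img - lo) / (hi - lo) * levels)) + 1L, levels)
  q <- matrix(q, nrow(img), ncol(img))
  offs <- list(offset)
  if (symmetric) offs <- c(offs, list(-offset))
  P <- matrix(0, levels, levels)
  for (off in offs)
    for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q))
        P[q[r, cc], q[r2, c2]] <- P[q[r, cc], q[r2, c2]] + 1
    }
  P <- P / sum(P)
  lev <- 0:(levels - 1)
  I <- matrix(lev, levels, levels); J <- t(I)
  mi <- sum(lev * rowSums(P)); mj <- sum(lev * colSums(P))
  si <- sqrt(sum((lev - mi)^2 * rowSums(P)))
  sj <- sqrt(sum((lev - mj)^2 * colSums(P)))
  list(contrast = sum(P * (I - J)^2), energy = sum(P^2),
       homogeneity = sum(P / (1 + abs(I - J))),
       correlation = if (si > 0 && sj > 0)
         sum((I - mi) * (J - mj) * P) / (si * sj) else NA_real_)
}
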