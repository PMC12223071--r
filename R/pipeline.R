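# End-to-end demo orchestration: simulate -> preprocess -> segment ->
# features -> select -> federated train (with ledger) -> evaluate, under one
# config with a single master seed fanned out per stage.

#' Fused feature table for a list of scans
#'
#' Handcrafted GLCM/first-order features plus globally average-pooled deep
#' backbone features, fused per scan into one named row.
#'
#' @param dataset List of `labeled_scan`s.
#' @param extractor Deep-feature extractor (see [deep_feature_extractor()]);
#'   `NULL` builds one deterministically from `seed`.
#' @param alpha,beta Fusion weights for the deep and handcrafted blocks.
#' @param seed Seed for the default extractor.
#' @return List: `X` (numeric matrix, one scan per row), `y` (labels),
#'   `meta` (data frame: id, label, tumor_type, client_id, modality).
#' @export
extract_feature_table <- function(dataset, extractor = NULL, alpha = 1,
                                  beta = 1, seed = 1L) {
  if (is.null(extractor))
    extractor <- deep_feature_extractor(
      input_size = nrow(dataset[[1]]$image),
      seed = derive_seed(seed, "deep-extractor"))
  rows <- lapply(dataset, function(s) {
    fused <- fuse_features(extractor(s$image), handcrafted_features(s),
                           alpha = alpha, beta = beta)
    stats::setNames(fused$values, fused$names)
  })
  X <- do.call(rbind, rows)
  meta <- data.frame(
    id = vapply(dataset, function(s) s$id %||% NA_character_, ""),
    label = vapply(dataset, `[[`, "", "label"),
    tumor_type = vapply(dataset, `[[`, "", "tumor_type"),
    client_id = vapply(dataset, `[[`, "", "client_id"),
    modality = vapply(dataset, `[[`, "", "modality"),
    stringsAsFactors = FALSE)
  list(X = X, y = meta$label, meta = meta)
}

#' Write a feature table as tab-separated text
#'
#' @param table A list from [extract_feature_table()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  df <- cbind(table$meta, as.data.frame(table$X))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

default_run_config <- function() {
  list(
    seed = 1L,
    out = NULL,
    simulate = list(n = 240, tumor_fraction = 0.5, pseudo_fraction = 0.4,
                    noise_sigma = 0.03,
                    # aggregate tumor-type composition of the five-client
                    # cohort, so heterogeneous client mixes are satisfiable
                    type_mix = c("glioma-like" = 0.48,
                                 "meningioma-like" = 0.23,
                                 "pituitary-like" = 0.29)),
    preprocess = list(enabled = TRUE, n_iter = 5, kappa = 0.1, lam = 0.2),
    segmentation = list(enabled = FALSE, epochs = 3, train_n = 120),
    selection = list(enabled = TRUE, T_max = 20, M = 15, w = 0.9),
    federated = list(K = 5, rounds = 10, local_epochs = 3,
                     dropout_rate = 0, noise_rate = 0, eval_fraction = 0.25),
    client_scale = NULL)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Validate a pipeline run config
#'
#' @param config Nested list (e.g. parsed from YAML); missing entries take
#'   defaults.
#' @return Character vector of violations, each naming the offending key;
#'   empty when the config is acceptable.
#' @export
validate_config <- function(config = list()) {
  cfg <- merge_config(default_run_config(), config)
  v <- character(0)
  chk <- function(cond, msg) if (!cond) v <<- c(v, msg)
  chk(is.numeric(cfg$seed) && is.finite(cfg$seed), "seed: must be set")
  chk(cfg$simulate$n > 0, "simulate.n: must be > 0")
  chk(cfg$simulate$tumor_fraction >= 0 && cfg$simulate$tumor_fraction <= 1,
      "simulate.tumor_fraction: must be in [0, 1]")
  chk(cfg$federated$dropout_rate >= 0 && cfg$federated$dropout_rate <= 1,
      "federated.dropout_rate: must be in [0, 1]")
  chk(cfg$federated$noise_rate >= 0 && cfg$federated$noise_rate <= 1,
      "federated.noise_rate: must be in [0, 1]")
  chk(cfg$federated$K >= 1, "federated.K: must be >= 1")
  if (isTRUE(cfg$segmentation$enabled)) {
    sz <- 64
    chk(sz %% 2^3 == 0,
        "segmentation.depth: input_size must be divisible by 2^depth")
  }
  v
}

#' Run the end-to-end demo pipeline
#'
#' Generates phantoms (plus pseudo-modality channel), preprocesses them,
#' optionally trains the tiny segmentation U-Net, extracts and fuses
#' features, selects features with the hybrid optimizer, partitions clients
#' and runs the federated simulation with ledger logging, then evaluates the
#' final global model on a held-out set of real (CT) scans.
#'
#' @param config Nested list; see `validate_config()`. Unset entries take
#'   defaults.
#' @return A run manifest: per-stage outputs, content digests, wall-clock
#'   seconds, and final metrics.
#' @export
run_pipeline <- function(config = list()) {
  viol <- validate_config(config)
  if (length(viol)) stop("invalid config:\n  ", paste(viol, collapse = "\n  "))
  cfg <- merge_config(default_run_config(), config)
  seed <- as.integer(cfg$seed)
  manifest <- list(config = cfg, stages = list())
  stage <- function(name, expr, digest_of = identity) {
    t0 <- Sys.time()
    out <- expr
    manifest$stages[[name]] <<- list(
      digest = digest::digest(digest_of(out), algo = "sha256"),
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  dataset <- stage("simulate", {
    sp <- phantom_spec(noise_sigma = cfg$simulate$noise_sigma)
    ds <- generate_dataset(cfg$simulate$n, cfg$simulate$tumor_fraction, sp,
                           seed = derive_seed(seed, "simulate"),
                           type_mix = cfg$simulate$type_mix)
    n_pseudo <- round(cfg$simulate$pseudo_fraction * length(ds))
    idx <- with_seed(derive_seed(seed, "pseudo"),
                     sample(length(ds), n_pseudo))
    pseudo <- lapply(ds[idx], make_pseudo_modality)
    ok <- vapply(pseudo, function(s)
      quality_gate(s$image, ds[[match(sub("-pmri$", "", s$id),
                                      vapply(ds, `[[`, "", "id"))]]$image,
                   ssim_min = 0.5, psnr_min = 10)$accept, logical(1))
    c(ds, pseudo[ok])
  })

  if (isTRUE(cfg$preprocess$enabled)) {
    dataset <- stage("preprocess", {
      dp <- diffusion_params(cfg$preprocess$n_iter, cfg$preprocess$kappa,
                             cfg$preprocess$lam)
      lapply(dataset, function(s) {
        img <- anisotropic_diffusion(s$image, dp)
        s$image <- minmax_normalize(img, 0, 1, const_fill = 0)
        s
      })
    })
  }

  seg <- NULL
  if (isTRUE(cfg$segmentation$enabled)) {
    seg <- stage("segmentation", {
      tumor_ct <- Filter(function(s) s$modality == "ct", dataset)
      tr <- tumor_ct[seq_len(min(cfg$segmentation$train_n, length(tumor_ct)))]
      train_segmenter(tr, segnet_config(), epochs = cfg$segmentation$epochs,
                      seed = derive_seed(seed, "seg"))
    })
  }

  feats <- stage("features", {
    ft <- extract_feature_table(dataset, seed = seed)
    # standardize once over the whole simulated population; downstream
    # selection and classification consume z-scored features
    ft$X <- scale(ft$X)
    ft$X[!is.finite(ft$X)] <- 0
    ft
  })

  sel <- NULL
  keep <- rep(TRUE, ncol(feats$X))
  if (isTRUE(cfg$selection$enabled)) {
    sel <- stage("selection", {
      select_features(feats$X, feats$y,
                      hgboa_params(T_max = cfg$selection$T_max,
                                   M = cfg$selection$M,
                                   seed = derive_seed(seed, "hgboa")),
                      w = cfg$selection$w)
    })
    keep <- sel$mask
  }

  fl <- stage("federated", {
    is_ct <- feats$meta$modality == "ct"
    n_eval <- round(cfg$federated$eval_fraction * sum(is_ct))
    eval_idx <- with_seed(derive_seed(seed, "eval-split"),
                          sample(which(is_ct), n_eval))
    pool_idx <- setdiff(seq_along(dataset), eval_idx)
    # largest feasible cohort scale: back off geometrically if a type pool
    # runs short (finite pools fluctuate binomially around the target mix)
    sc <- cfg$client_scale %||% (0.9 * length(pool_idx) / 3000)
    parts <- NULL
    for (try in 1:6) {
      parts <- tryCatch(
        partition_clients(dataset[pool_idx], default_client_profiles(sc),
                          seed = derive_seed(seed, "partition")),
        error = function(e) NULL)
      if (!is.null(parts)) break
      sc <- sc * 0.85
    }
    if (is.null(parts))
      stop("federated stage: could not find a feasible client partition")
    ids <- vapply(dataset, function(s) s$id %||% "", "")
    client_sets <- lapply(parts, function(cl) {
      ix <- match(vapply(cl, `[[`, "", "id"), ids)
      list(X = feats$X[ix, keep, drop = FALSE], y = feats$y[ix],
           client_id = cl[[1]]$client_id)
    })
    flc <- fl_config(K = length(client_sets), rounds = cfg$federated$rounds,
                     local_epochs = cfg$federated$local_epochs,
                     dropout_rate = cfg$federated$dropout_rate,
                     noise_rate = cfg$federated$noise_rate,
                     seed = derive_seed(seed, "fl"))
    clfc <- classifier_config(mode = "features", input_dim = sum(keep))
    res <- run_simulation(flc, client_sets, clfc,
                          eval_set = list(X = feats$X[eval_idx, keep,
                                                      drop = FALSE],
                                          y = feats$y[eval_idx]))
    res$eval_idx <- eval_idx
    res
  }, digest_of = function(r)
    # block timestamps are wall-clock; digest only the reproducible payload
    list(weights = r$weights,
         digests = vapply(r$history, `[[`, "", "digest")))

  metrics <- stage("evaluate", {
    pr <- predict_capsule(fl$model,
                          feats$X[fl$eval_idx, keep, drop = FALSE])
    cm <- confusion(pr$label, feats$y[fl$eval_idx], positive = "tumor")
    classification_metrics(cm)
  })

  manifest$metrics <- metrics
  manifest$selection <- if (is.null(sel)) NULL else
    list(frr = sel$frr, fitness = sel$fitness, accuracy = sel$accuracy)
  manifest$ledger_valid <- verify_chain(fl$ledger)$valid
  manifest$segmentation_loss <- if (is.null(seg)) NULL else
    utils::tail(seg$loss_trace, 1)

  if (!is.null(cfg$out)) {
    dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
    write_ledger(fl$ledger, file.path(cfg$out, "ledger.jsonl"))
    write_feature_table(feats, file.path(cfg$out, "features.tsv"))
    jsonlite::write_json(list(metrics = metrics,
                              stages = manifest$stages,
                              ledger_valid = manifest$ledger_valid),
                         file.path(cfg$out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  manifest
}
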