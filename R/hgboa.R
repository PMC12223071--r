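# Hybrid Gorilla-Badger optimization: gorilla-troops exploration with a
# honey-badger-style exploitation branch, plus a binarizing wrapper for
# feature selection reporting fitness and the feature-reduction rate (FRR).

#' Continuous search space
#'
#' @param dim Dimensionality.
#' @param lb,ub Scalar or per-dimension bounds, `lb < ub` elementwise.
#' @return A `search_space`.
#' @export
search_space <- function(dim, lb = 0, ub = 1) {
  lb <- rep_len(as.numeric(lb), dim)
  ub <- rep_len(as.numeric(ub), dim)
  if (!all(lb < ub)) stop("lb must be < ub elementwise")
  structure(list(dim = as.integer(dim), lb = lb, ub = ub),
            class = "search_space")
}

#' Optimizer control parameters
#'
#' @param T_max Iterations.
#' @param M Population size (>= 2).
#' @param p Probability gate for the uniform-reinitialization exploration
#'   branch.
#' @param beta Threshold on `|C|` switching between the follow-silverback
#'   and fight exploitation updates.
#' @param seed RNG seed.
#' @param bound_handling `"clip"` or `"reflect"`.
#' @return An `hgboa_params`.
#' @export
hgboa_params <- function(T_max = 100, M = 30, p = 0.03, beta = 0.8,
                         seed = 1L, bound_handling = c("clip", "reflect")) {
  if (T_max < 1) stop("T_max must be >= 1")
  if (M < 2) stop("M must be >= 2")
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  structure(list(T_max = as.integer(T_max), M = as.integer(M), p = p,
                 beta = beta, seed = as.integer(seed),
                 bound_handling = match.arg(bound_handling)),
            class = "hgboa_params")
}

#' Sinusoidal follow-silverback amplitude schedule
#'
#' `delta = sin(2.5 - t/T)` (radians); increases from `sin(2.5)` at `t = 0`
#' to `sin(1.5)` at `t = T`.
#'
#' @param t Current iteration (0-based allowed).
#' @param T_max Total iterations (> 0).
#' @return Scalar `delta`.
#' @export
delta_schedule <- function(t, T_max) {
  if (T_max <= 0) stop("T_max must be > 0")
  sin(2.5 - t / T_max)
}

#' Exponentially decaying fight-update amplitude
#'
#' `alpha = 2 exp(-t/T)`; strictly decreasing from 2 to 2/e.
#'
#' @inheritParams delta_schedule
#' @return Scalar `alpha`.
#' @export
alpha_schedule <- function(t, T_max) {
  if (T_max <= 0) stop("T_max must be > 0")
  2 * exp(-t / T_max)
}

#' Follow-the-silverback position update
#'
#' `delta * rand1 * (|GX - X_sb| + GX)` elementwise, one `rand1` per update.
#'
#' @param gx Agent position.
#' @param x_sb Silverback (best) position.
#' @param t,T_max Iteration schedule inputs.
#' @param rand1 Optional forced uniform draw (tests); default drawn from the
#'   active RNG stream.
#' @return Proposed position (before bound handling).
#' @export
follow_silverback <- function(gx, x_sb, t, T_max, rand1 = stats::runif(1)) {
  delta_schedule(t, T_max) * rand1 * (abs(gx - x_sb) + gx)
}

#' Fight-for-females position update
#'
#' `X_sb + F * rand2 * alpha * (X_sb - GX)` with flag `F` in `{-1, 1}`.
#'
#' @inheritParams follow_silverback
#' @param F_flag -1 or 1.
#' @param rand2 Optional forced uniform draw.
#' @return Proposed position (before bound handling).
#' @export
fight_update <- function(gx, x_sb, t, T_max, F_flag,
                         rand2 = stats::runif(1)) {
  if (!F_flag %in% c(-1, 1)) stop("F_flag must be -1 or 1")
  x_sb + F_flag * rand2 * alpha_schedule(t, T_max) * (x_sb - gx)
}

#' Three-branch exploration update
#'
#' One uniform draw `rand` selects the branch: `rand >= p` re-draws the
#' position uniformly in the bounds; else `rand >= 0.5` moves toward a random
#' member with amplitude terms `(r2 - C) X_r + L H`; else applies the
#' local-escape move `GX - gamma r L (L (GX - GX_r) + r3 (GX - GX_r))` with
#' `gamma = 2 rand - 1`. The auxiliary terms follow the gorilla-troops
#' conventions: `C = F (1 - t/T)` with `F = cos(2 r4) + 1`, `L = C l`
#' (`l ~ U[-1,1]`), `H = Z * GX` (`Z ~ U[-C, C]`).
#'
#' @param gx Agent position.
#' @param population `M x dim` matrix of all agent positions.
#' @param space A [search_space()].
#' @param t,T_max Schedule inputs.
#' @param p Branch-gate probability.
#' @return Proposed position (before bound handling).
#' @export
explore_update <- function(gx, population, space, t, T_max, p) {
  if (nrow(population) < 2) stop("population size must be >= 2")
  rand <- stats::runif(1)
  r4 <- stats::runif(1)
  C <- (cos(2 * r4) + 1) * (1 - t / T_max)
  l <- stats::runif(1, -1, 1)
  L <- C * l
  if (rand >= p) {
    (space$ub - space$lb) * stats::runif(space$dim) + space$lb
  } else if (rand >= 0.5) {
    r2 <- stats::runif(1)
    Z <- stats::runif(space$dim, -C, C)
    xr <- population[sample.int(nrow(population), 1), ]
    (r2 - C) * xr + L * (Z * gx)
  } else {
    gamma <- 2 * rand - 1
    r <- stats::runif(1)
    r3 <- stats::runif(1)
    gxr <- population[sample.int(nrow(population), 1), ]
    gx - gamma * r * L * (L * (gx - gxr) + r3 * (gx - gxr))
  }
}

apply_bounds <- function(x, space, how) {
  if (how == "clip") return(pmin(pmax(x, space$lb), space$ub))
  # reflect once then clip any remaining excursions
  over <- x > space$ub
  under <- x < space$lb
  x[over] <- 2 * space$ub[over] - x[over]
  x[under] <- 2 * space$lb[under] - x[under]
  pmin(pmax(x, space$lb), space$ub)
}

#' Run the hybrid Gorilla-Badger optimizer (minimization)
#'
#' Each iteration every agent receives an exploration proposal and then an
#' exploitation proposal (follow-silverback when `|C| >= beta`, else the
#' fight update), each accepted greedily when it improves the agent's
#' fitness. The best-so-far trace is therefore monotone non-increasing.
#' Deterministic under `params$seed`.
#'
#' @param objective Function position -> finite scalar to minimize.
#' @param space A [search_space()].
#' @param params An [hgboa_params()].
#' @return List: `best` (position), `best_fitness`, `trace` (best-so-far per
#'   iteration, length `T_max`), `evals` (objective evaluation count).
#' @export
hgboa_optimize <- function(objective, space, params = hgboa_params()) {
  safe_obj <- function(x) {
    v <- objective(x)
    if (!is.finite(v))
      stop("non-finite objective value at position ",
           paste(signif(x, 4), collapse = ", "))
    v
  }
  with_seed(params$seed, {
    M <- params$M; Tm <- params$T_max
    GX <- sapply(seq_len(space$dim), function(d)
      stats::runif(M, space$lb[d], space$ub[d]))
    GX <- matrix(GX, M, space$dim)
    fit <- apply(GX, 1, safe_obj)
    evals <- M
    best_i <- which.min(fit)
    x_sb <- GX[best_i, ]; f_sb <- fit[best_i]
    trace <- numeric(Tm)
    for (t in seq_len(Tm)) {
      for (i in seq_len(M)) {
        # exploration proposal
        cand <- explore_update(GX[i, ], GX, space, t, Tm, params$p)
        cand <- apply_bounds(cand, space, params$bound_handling)
        fc <- safe_obj(cand); evals <- evals + 1
        if (fc < fit[i]) { GX[i, ] <- cand; fit[i] <- fc }
        # exploitation proposal
        r4 <- stats::runif(1)
        C <- (cos(2 * r4) + 1) * (1 - t / Tm)
        cand <- if (abs(C) >= params$beta) {
          follow_silverback(GX[i, ], x_sb, t, Tm)
        } else {
          F_flag <- if (stats::runif(1) < 0.5) -1 else 1
          fight_update(GX[i, ], x_sb, t, Tm, F_flag)
        }
        cand <- apply_bounds(cand, space, params$bound_handling)
        fc <- safe_obj(cand); evals <- evals + 1
        if (fc < fit[i]) { GX[i, ] <- cand; fit[i] <- fc }
        if (fit[i] < f_sb) { f_sb <- fit[i]; x_sb <- GX[i, ] }
      }
      trace[t] <- f_sb
    }
    list(best = x_sb, best_fitness = f_sb, trace = trace, evals = evals)
  })
}

#' Feature-reduction rate
#'
#' Percentage of candidate features discarded by a selection mask.
#'
#' @param mask Logical selection vector.
#' @return `100 * (1 - selected/total)`.
#' @export
feature_reduction_rate <- function(mask) {
  if (length(mask) == 0) stop("empty mask")
  100 * (1 - sum(mask) / length(mask))
}

# leave-grouped-out CV accuracy of a nearest-mean classifier on X[, mask]
nearest_mean_cv <- function(X, y, mask, folds) {
  Xs <- X[, mask, drop = FALSE]
  classes <- levels(y)
  correct <- 0
  for (f in unique(folds)) {
    tr <- folds != f
    mu <- lapply(classes, function(cl)
      colMeans(Xs[tr & y == cl, , drop = FALSE]))
    Xt <- Xs[!tr, , drop = FALSE]
    d <- sapply(mu, function(m)
      rowSums(sweep(Xt, 2, m)^2))
    d <- matrix(d, nrow(Xt), length(classes))
    d[!is.finite(d)] <- Inf # class absent from a training fold
    pred <- classes[max.col(-d, ties.method = "first")]
    correct <- correct + sum(pred == y[!tr])
  }
  correct / nrow(X)
}

#' Wrapper feature selection with the hybrid optimizer
#'
#' Continuous agent positions in `[0,1]^d` are binarized at 0.5; internal
#' fitness (minimized) is `w (1 - cv_accuracy) + (1 - w) selected/total`,
#' with empty masks penalized at fitness 1. The inner evaluator is a
#' nearest-mean classifier under k-fold cross-validation on the training
#' data only. Features are standardized (train-set statistics) before
#' evaluation.
#'
#' @param X Numeric feature matrix (rows = samples).
#' @param y Class labels (>= 2 classes).
#' @param params An [hgboa_params()].
#' @param w Accuracy weight in `[0, 1]` (default 0.9).
#' @param cv_folds Inner cross-validation folds.
#' @return List: `mask` (logical), `fitness` (reported, higher-better
#'   `1 - internal`), `frr` (percent), `accuracy` (inner CV accuracy of the
#'   selected mask), `trace`.
#' @export
select_features <- function(X, y, params = hgboa_params(T_max = 30, M = 20),
                            w = 0.9, cv_folds = 3) {
  y <- factor(y)
  if (nlevels(y) < 2) stop("need >= 2 classes")
  if (ncol(X) < 2) stop("need >= 2 features")
  X <- scale(X)
  X[!is.finite(X)] <- 0
  folds <- with_seed(derive_seed(params$seed, "cv"),
                     sample(rep(seq_len(cv_folds), length.out = nrow(X))))
  d <- ncol(X)
  objective <- function(pos) {
    mask <- pos >= 0.5
    if (!any(mask)) return(1)
    acc <- nearest_mean_cv(X, y, mask, folds)
    w * (1 - acc) + (1 - w) * sum(mask) / d
  }
  res <- hgboa_optimize(objective, search_space(d, 0, 1), params)
  mask <- res$best >= 0.5
  acc <- if (any(mask)) nearest_mean_cv(X, y, mask, folds) else NA_real_
  list(mask = mask, fitness = 1 - res$best_fitness,
       frr = feature_reduction_rate(mask), accuracy = acc,
       trace = res$trace)
}
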