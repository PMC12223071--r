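#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the Mersenne-Twister generator with
#' `seed`, evaluates `expr`, and restores the previous state. All stochastic
#' functions in the package route their randomness through this helper so a
#' call never perturbs the user's global RNG stream.
#'
#' @param seed Integer seed (must fit in a 32-bit signed integer).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed and a label
#'
#' Hashes `master` together with the supplied labels (SHA-256) and folds the
#' first eight hex digits into a non-negative integer below 2^31. Used to fan
#' one master seed out to per-scan, per-stage, per-client and per-round seeds
#' so that stages rerun in isolation reproduce the full-pipeline stream.
#'
#' @param master Integer master seed.
#' @param ... Labels (coerced to character) identifying the consumer.
#' @return A single integer in `[0, 2^31 - 1]`.
#' @export
#' @examples
#' derive_seed(42, "phantom", 3)
derive_seed <- function(master, ...) {
  key <- paste(c(format(as.integer(master)), vapply(list(...), function(x)
    paste(format(x), collapse = ","), character(1))), collapse = "|")
  hex <- digest::digest(key, algo = "sha256", serialize = FALSE)
  as.integer(strtoi(substr(hex, 1, 7), base = 16L)) # 28 bits < 2^31
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_binary <- function(m, what = "mask") {
  if (!is.matrix(m) && !is.array(m)) stop(what, " must be a matrix")
  v <- as.vector(m)
  if (!(is.logical(v) || all(v %in% c(0, 1))))
    stop(what, " must be binary (logical or 0/1)")
  invisible(TRUE)
}

as_binary <- function(m) {
  storage.mode(m) <- "logical"
  m
}
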