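# Append-only SHA-256 hash chain of per-round global-model digests with a
# fixed authority (validator) set: a desk-scale stand-in for a private
# proof-of-authority blockchain.

GENESIS_HASH <- strrep("0", 64)

sha256_hex <- function(x) digest::digest(x, algo = "sha256",
                                         serialize = FALSE)

#' Create an empty ledger
#'
#' @param authority_set Character vector of authorized validator ids
#'   (default: five hospital nodes).
#' @param fixed_time Optional fixed ISO-8601 timestamp string used for every
#'   block (golden-file/determinism mode); `NULL` uses the wall clock.
#' @return A `model_ledger`.
#' @export
new_ledger <- function(authority_set = paste0("hospital-", 1:5),
                       fixed_time = NULL) {
  structure(list(chain = list(), authority_set = authority_set,
                 fixed_time = fixed_time),
            class = "model_ledger")
}

# canonical serialization of a weight vector: UTF-8 registry prefix followed
# by little-endian IEEE-754 doubles in registry order
serialize_weights <- function(weights, registry = NULL) {
  if (length(weights) && !all(is.finite(weights)))
    stop("non-finite weights rejected")
  prefix <- if (is.null(registry)) raw(0)
  else charToRaw(paste(vapply(registry, function(r)
    paste0(r$name, ":", paste(r$dim, collapse = "x")), character(1)),
    collapse = ";"))
  c(prefix, writeBin(as.numeric(weights), raw(), size = 8,
                     endian = "little"))
}

#' SHA-256 digest of a model weight vector
#'
#' Hashes the canonical serialization (optional shape-registry prefix, then
#' little-endian 64-bit floats in order), so digests are stable across
#' processes and platforms.
#'
#' @param weights Flat numeric parameter vector (finite).
#' @param registry Optional shape registry (as produced during flattening).
#' @return 64-character lowercase hex digest.
#' @export
digest_weights <- function(weights, registry = NULL) {
  sha256_hex(serialize_weights(weights, registry))
}

block_header_hash <- function(index, round, prev_hash, payload_digest,
                              validator_id, timestamp) {
  sha256_hex(paste(index, round, prev_hash, payload_digest, validator_id,
                   timestamp, sep = "|"))
}

#' Append a block to the ledger
#'
#' The validator must belong to the authority set and the round must be
#' strictly greater than the last logged round (append-only, monotone).
#'
#' @param ledger A `model_ledger`.
#' @param round Federated round number.
#' @param payload_digest Hex digest of the model payload
#'   (see [digest_weights()]).
#' @param validator_id Member of the authority set.
#' @return The updated ledger (the new block is `tail(ledger$chain, 1)`).
#' @export
append_block <- function(ledger, round, payload_digest, validator_id) {
  stopifnot(inherits(ledger, "model_ledger"))
  if (!validator_id %in% ledger$authority_set)
    stop("unauthorized validator: ", validator_id)
  n <- length(ledger$chain)
  if (n > 0 && round <= ledger$chain[[n]]$round)
    stop("round must be strictly increasing")
  prev <- if (n == 0) GENESIS_HASH else ledger$chain[[n]]$block_hash
  ts <- ledger$fixed_time %||%
    format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  blk <- list(index = n, round = as.integer(round), prev_hash = prev,
              payload_digest = payload_digest,
              validator_id = validator_id, timestamp = ts)
  blk$block_hash <- block_header_hash(blk$index, blk$round, blk$prev_hash,
                                      blk$payload_digest, blk$validator_id,
                                      blk$timestamp)
  ledger$chain[[n + 1]] <- blk
  ledger
}

#' Verify the full hash chain
#'
#' Recomputes every block hash and link; reports the first violation.
#' Never throws.
#'
#' @param ledger A `model_ledger`.
#' @return List: `valid` (logical); on failure also `index` and `reason`.
#' @export
verify_chain <- function(ledger) {
  prev <- GENESIS_HASH
  for (i in seq_along(ledger$chain)) {
    b <- ledger$chain[[i]]
    if (!identical(b$index, i - 1L) && b$index != i - 1)
      return(list(valid = FALSE, index = i - 1, reason = "index mismatch"))
    if (!identical(b$prev_hash, prev))
      return(list(valid = FALSE, index = i - 1, reason = "broken link"))
    if (!b$validator_id %in% ledger$authority_set)
      return(list(valid = FALSE, index = i - 1,
                  reason = "unauthorized validator"))
    rh <- block_header_hash(b$index, b$round, b$prev_hash, b$payload_digest,
                            b$validator_id, b$timestamp)
    if (!identical(rh, b$block_hash))
      return(list(valid = FALSE, index = i - 1, reason = "hash mismatch"))
    prev <- b$block_hash
  }
  list(valid = TRUE)
}

#' Audit one round's logged model digest
#'
#' Recomputes the digest of the supplied weights and compares it with the
#' payload digest logged for that round.
#'
#' @param ledger A `model_ledger`.
#' @param round Round number (must exist in the chain).
#' @param weights Flat weight vector to audit.
#' @param registry Optional shape registry used at logging time.
#' @return `TRUE` if the digests match, `FALSE` otherwise.
#' @export
audit_round <- function(ledger, round, weights, registry = NULL) {
  rounds <- vapply(ledger$chain, `[[`, numeric(1), "round")
  i <- match(round, rounds)
  if (is.na(i)) stop("unknown round: ", round)
  identical(digest_weights(weights, registry),
            ledger$chain[[i]]$payload_digest)
}

#' Write a ledger as JSON lines (one block per line)
#'
#' @param ledger A `model_ledger`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_ledger <- function(ledger, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(authority_set = ledger$authority_set),
                              auto_unbox = TRUE), con)
  for (b in ledger$chain)
    writeLines(jsonlite::toJSON(b, auto_unbox = TRUE), con)
  invisible(path)
}

#' Read a ledger from JSON lines
#'
#' @param path File written by [write_ledger()].
#' @return A `model_ledger`.
#' @export
read_ledger <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  led <- new_ledger(authority_set = hdr$authority_set)
  for (ln in lines[-1]) {
    b <- jsonlite::fromJSON(ln)
    b$index <- as.integer(b$index)
    led$chain[[length(led$chain) + 1]] <- b
  }
  led
}
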