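#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# package-level scratch environment (memoized probe molecules etc.)
ghstox_env <- new.env(parent = emptyenv())

# Deterministic per-stage seed derived from a global seed and a stage name.
# Kept strictly below 2^31 so it is always a valid input to set.seed().
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

# round-half-up, used for per-class test-set quotas
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# FNV-1a hash of a character scalar, returned as hex; used to fingerprint
# run configurations in manifests without external digest dependencies.
fnv1a_hex <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# Stratified fold assignment: returns integer fold ids 1..k, every fold
# containing members of both classes whenever the class sizes allow it.
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}
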