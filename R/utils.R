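# Deterministic seed streams and small internal helpers.

#' Derive a child seed from a parent seed and a stream index
#'
#' All randomness in the package flows from one top-level seed. Nested stages
#' (outer fold, bootstrap replicate, inner fold assignment, ...) each get an
#' independent, reproducible stream by mixing the parent seed with integer
#' tags, so any sub-computation can be re-run in isolation.
#'
#' @param seed integer parent seed (< 2^31).
#' @param ... integer tags identifying the stream (e.g. fold index,
#'   bootstrap index).
#' @return an integer seed in `[1, 2147483628]`.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483629  # prime below 2^31
  s <- as.double(seed %% m)
  for (k in c(...)) {
    # affine mix; all intermediates stay below 2^53 so doubles are exact
    s <- (s * 48271 + as.double(k) * 30269 + 11) %% m
  }
  as.integer(s + 1)
}

# Run `expr` under `set.seed(seed)` and restore the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# FNV-1a hash of a character representation; used for run manifests.
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
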