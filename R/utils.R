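# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stream-specific seed from a master seed
#'
#' All stochastic steps in the package draw their randomness from a single
#' integer master seed through named streams, so that e.g. adding noise to
#' phenotypes never perturbs the genotype draw. The derivation is a Lehmer
#' step followed by a polynomial hash of the stream name, everything modulo
#' 2^31 - 1 (safe in double arithmetic).
#'
#' @param seed integer master seed.
#' @param stream character stream name, e.g. `"genotypes"`.
#' @return an integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  s <- (s * 48271) %% m
  for (ch in utf8ToInt(stream)) s <- (s * 31 + ch) %% m
  as.integer(s %% (m - 2) + 1)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
# A NULL seed means "use the current RNG stream as-is".
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# consistent error prefix for user-facing validation failures
bca_stop <- function(...) stop(..., call. = FALSE)
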