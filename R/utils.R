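# Internal helpers shared across modules.

#' Derive a reproducible substream seed
#'
#' Fans a single user-facing seed out into independent per-stage seeds so
#' that pipeline stages can be regenerated in isolation without replaying
#' the whole random stream. Purely arithmetic; no RNG state is touched.
#'
#' @param seed integer master seed.
#' @param k non-negative integer substream index.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(k))
  m <- 2147483647  # 2^31 - 1, keeps products within double precision
  as.integer(((abs(seed) %% m) * 69621 + k * 7919 + 1) %% m)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so callers never perturb the global
#' RNG state.
#'
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stop() with a class so callers can condition on error kinds
xo_stop <- function(msg, class) {
  stop(structure(class = c(class, "xomics_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x == floor(x) && x > 0

is_fraction <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 0 && x <= 1
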