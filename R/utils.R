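# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores whatever state was in place before the call, so simulations are
#' pure functions of their arguments without clobbering the caller's stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic sub-seed derivation; stays well below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset)) %% 2147483399) + 1L
}

# Largest-remainder apportionment of n items over proportions, each class >= min_each.
apportion <- function(n, prop, min_each = 1L) {
  k <- length(prop)
  stopifnot(n >= k * min_each)
  raw <- n * prop / sum(prop)
  base <- pmax(floor(raw), min_each)
  while (sum(base) > n) {  # min_each may overshoot when a class is tiny
    i <- which.max(base - raw)
    base[i] <- base[i] - 1L
  }
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - floor(raw)
    ord <- order(frac, decreasing = TRUE)
    take <- rep_len(ord, rem)
    for (i in take) base[i] <- base[i] + 1L
  }
  as.integer(base)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("deercomp_input_error", "error")))
}
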