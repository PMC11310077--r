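#' Deterministic seed streams
#'
#' Reproducibility across the pipeline must not depend on the order in which
#' records, samples or resamples happen to be visited.  Every randomized
#' operation therefore derives its own seed from the master seed plus a path
#' of integer/character labels (a counter-based splitting rule), and calls
#' `set.seed()` locally.
#'
#' The mixer is a simple multiply-add hash over a Mersenne-prime modulus,
#' computed in doubles (all intermediates stay below 2^53, and results below
#' 2^31 so they are valid R integer seeds).
#'
#' @param seed master seed (integer).
#' @param ... path labels: integers or strings.
#' @return an integer in [1, 2^31 - 2] usable with [set.seed()].
#' @keywords internal
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1
  h <- (as.numeric(seed) %% m)
  for (lab in list(...)) {
    if (is.character(lab)) {
      for (v in utf8ToInt(lab)) h <- (h * 69069 + v + 1) %% m
    } else {
      for (v in as.numeric(lab)) h <- (h * 69069 + (v %% m) + 1) %% m
    }
  }
  # final avalanche round so short paths do not collide with their prefixes
  h <- (h * 69069 + 12345) %% m
  as.integer(h %% (m - 2) + 1)
}

#' Evaluate an expression under a locally derived seed
#'
#' Saves and restores the caller's RNG state, so library code never perturbs
#' user-level randomness.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
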