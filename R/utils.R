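## Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so library functions never clobber a caller's stream.
#'
#' @param seed single non-negative integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, code) {
  seed <- checkSeed(seed)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

## Per-repetition child seed: master XOR repetition index. Keeps every
## repetition independently reproducible and all seeds inside 32-bit range.
childSeed <- function(master, i) {
  bitwXor(as.integer(master), as.integer(i))
}

checkSeed <- function(seed) {
  if (length(seed) != 1L || !is.finite(seed) || seed < 0 || seed != floor(seed)) {
    stop("'seed' must be a single non-negative integer", call. = FALSE)
  }
  if (seed >= 2^31) stop("'seed' must be below 2^31", call. = FALSE)
  as.integer(seed)
}

checkCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != floor(x) || x < min) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

checkProb <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  }
  as.numeric(x)
}

## Accept a DeficitVector or a bare numeric as the response.
asScores <- function(deficit, n = NULL) {
  y <- if (is(deficit, "DeficitVector")) deficitScores(deficit) else as.numeric(deficit)
  if (!all(is.finite(y))) stop("deficit scores must all be finite", call. = FALSE)
  if (!is.null(n) && length(y) != n) {
    stop(sprintf("deficit length (%d) does not match number of subjects (%d)",
                 length(y), n), call. = FALSE)
  }
  y
}
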