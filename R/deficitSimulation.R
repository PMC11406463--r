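#' Simulate a ground-truth deficit from region lesion loads
#'
#' The deficit equals the lesion load of one target region (single-region
#' ground truth) or a non-negative weighted combination of region loads
#' (complex ground truth), plus i.i.d. normal noise whose SD is `noiseK` times
#' the sample SD of that signal across the full cohort:
#' `scores = signal + eps`, `eps ~ N(0, (noiseK * SD(signal))^2)`.
#' The study's noise conditions are `noiseK = 0.2` (low) and `noiseK = 1.0`
#' (high). The signal SD is computed once on the full cohort, before any
#' subsampling, so the noise level is a fixed property of the simulation.
#'
#' @param loads a [LoadMatrix] for the full cohort.
#' @param region single target region id (mutually exclusive with `weights`).
#' @param weights numeric weight vector over all regions (non-negative; see
#'   [complexDeficitWeights()]).
#' @param noiseK non-negative noise multiplier k.
#' @param seed RNG seed; noise is drawn once per deficit and shared across all
#'   later subsampling repetitions.
#' @return A [DeficitVector] whose provenance records target, `noiseK`, seed,
#'   and the signal SD used.
#' @examples
#' X <- matrix(runif(50 * 4), 50, 4)
#' loads <- newLoadMatrix(X)
#' d <- simulateDeficit(loads, region = 2, noiseK = 0.2, seed = 1)
#' @export
simulateDeficit <- function(loads, region = NULL, weights = NULL,
                            noiseK = 0, seed = 1L) {
  stopifnot(is(loads, "LoadMatrix"))
  if (is.null(region) == is.null(weights)) {
    stop("exactly one of 'region' or 'weights' must be given", call. = FALSE)
  }
  if (length(noiseK) != 1L || !is.finite(noiseK) || noiseK < 0) {
    stop("'noiseK' must be a single non-negative number", call. = FALSE)
  }
  X <- loads@values
  n <- nrow(X)
  if (!is.null(region)) {
    region <- as.integer(region)
    col <- match(region, loads@regionIds)
    if (length(region) != 1L || is.na(col)) {
      stop("'region' must be a single valid region id", call. = FALSE)
    }
    signal <- X[, col]
    prov <- list(region = region, noiseK = noiseK, seed = checkSeed(seed))
  } else {
    if (length(weights) != ncol(X)) {
      stop("'weights' must have one entry per region", call. = FALSE)
    }
    if (any(!is.finite(weights)) || any(weights < 0)) {
      stop("'weights' must be finite and non-negative", call. = FALSE)
    }
    signal <- as.vector(X %*% weights)
    prov <- list(weights = as.numeric(weights), noiseK = noiseK,
                 seed = checkSeed(seed))
  }
  sdSignal <- sd(signal)
  if (sdSignal == 0 && noiseK > 0) {
    stop("signal has zero variance: the noise scale k * SD is undefined",
         call. = FALSE)
  }
  eps <- if (noiseK > 0) {
    withSeed(seed, rnorm(n, mean = 0, sd = noiseK * sdSignal))
  } else {
    numeric(n)
  }
  prov$sdSignal <- sdSignal
  new("DeficitVector",
      scores = setNames(signal + eps, rownames(X)),
      provenance = prov)
}
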