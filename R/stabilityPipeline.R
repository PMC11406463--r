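## The headline procedure: repeatedly subsample the cohort, run every mapper,
## and count per-region occurrences. Each repetition i uses the child seed
## masterSeed XOR i for both the subsample draw and the lasso fold partition,
## so single repetitions are independently reproducible.

builtinMappers <- function(config) {
  list(
    univariate = function(loadsSub, ySub, seed) {
      univariateMap(loadsSub, ySub, alpha = config@alpha)$selected
    },
    lasso = function(loadsSub, ySub, seed) {
      lassoCv(loadsSub, ySub, K = config@lassoFolds,
              gridSize = config@lassoGridSize, seed = seed,
              rule = config@lassoRule)$selected
    }
  )[config@mappers]
}

#' Run the subsample-and-map stability procedure
#'
#' For `nReps` repetitions, draws `subsampleSize` subjects without replacement
#' (study design: 100 draws of 120 of 180 subjects), runs every configured
#' mapper on the subsample, and records which regions each mapper implicated.
#' Both mappers see the same subsample in a repetition. A mapper failure on a
#' subsample (e.g. a constant deficit after subsampling) is recorded as an
#' empty selection with a warning, keeping the count denominator fixed at
#' `nReps`.
#'
#' @param loads the full-cohort [LoadMatrix].
#' @param deficit a [DeficitVector] or numeric score vector.
#' @param config a [StabilityConfig].
#' @param mappers optional named list of mapper functions
#'   `function(loadsSub, ySub, seed) -> logical(R)` overriding the built-in
#'   univariate/lasso mappers (used for testing and extensions).
#' @return A [StabilityTable].
#' @examples
#' loads <- newLoadMatrix(matrix(runif(40 * 6), 40, 6))
#' d <- simulateDeficit(loads, region = 3, noiseK = 0.2, seed = 1)
#' cfg <- stabilityConfig(nReps = 5, subsampleSize = 30, mappers = "univariate",
#'                        reportThreshold = 1, masterSeed = 9)
#' tab <- runStability(loads, d, cfg)
#' occurrenceCounts(tab, "univariate")
#' @export
runStability <- function(loads, deficit, config, mappers = NULL) {
  stopifnot(is(loads, "LoadMatrix"), is(config, "StabilityConfig"))
  X <- loads@values
  n <- nrow(X)
  R <- ncol(X)
  if (config@subsampleSize > n) {
    stop(sprintf("subsampleSize (%d) exceeds the cohort size (%d)",
                 config@subsampleSize, n), call. = FALSE)
  }
  y <- asScores(deficit, n)
  if (is.null(mappers)) mappers <- builtinMappers(config)
  if (is.null(names(mappers)) || any(names(mappers) == "")) {
    stop("'mappers' must be a named list of functions", call. = FALSE)
  }
  sel <- lapply(mappers, function(.) {
    matrix(FALSE, config@nReps, R,
           dimnames = list(NULL, sprintf("region_%d", loads@regionIds)))
  })
  for (i in seq_len(config@nReps)) {
    cs <- childSeed(config@masterSeed, i)
    idx <- withSeed(cs, sample.int(n, config@subsampleSize))
    loadsSub <- loads[idx, ]
    ySub <- y[idx]
    for (m in names(mappers)) {
      res <- tryCatch(
        as.logical(mappers[[m]](loadsSub, ySub, cs)),
        error = function(e) {
          warning(sprintf("repetition %d: mapper '%s' failed (%s); recording an empty selection",
                          i, m, conditionMessage(e)), call. = FALSE)
          rep(FALSE, R)
        })
      if (length(res) != R || anyNA(res)) {
        stop(sprintf("mapper '%s' must return %d non-missing logicals", m, R),
             call. = FALSE)
      }
      sel[[m]][i, ] <- res
    }
  }
  new("StabilityTable", selections = sel, regionIds = loads@regionIds,
      nReps = config@nReps, subsampleSize = config@subsampleSize,
      masterSeed = config@masterSeed)
}

## Mean Jaccard similarity over all repetition pairs. Two empty selections
## are identical sets: their Jaccard is taken as 1.
meanPairwiseJaccard <- function(S) {
  nR <- nrow(S)
  if (nR < 2L) return(NA_real_)
  Sm <- matrix(as.numeric(S), nrow(S), ncol(S))
  inter <- tcrossprod(Sm)
  sz <- rowSums(Sm)
  uni <- outer(sz, sz, "+") - inter
  jac <- ifelse(uni > 0, inter / uni, 1)
  mean(jac[upper.tri(jac)])
}

#' Summarize a stability run
#'
#' Produces, per mapper, the thresholded report — regions whose occurrence
#' count reaches `threshold`, sorted by count descending (ties by region id) —
#' and stability metrics: the occurrence frequency of every ground-truth
#' region, the mean number of selected non-truth regions per repetition, the
#' mean number of selections per repetition, and the mean pairwise Jaccard
#' similarity of the selected sets across repetitions (selection stability).
#'
#' @param table a [StabilityTable].
#' @param truth integer vector of ground-truth region ids; empty in
#'   measured-deficit mode, in which case sensitivity metrics are absent.
#' @param threshold minimum occurrence count for the report, in 0..nReps
#'   (typical reporting thresholds are 10 or 25 of 100 repetitions).
#' @return A list of class `"stabilitySummary"` with elements `report` and
#'   `metrics`, each a named list with one entry per mapper, plus `truth` and
#'   `threshold`.
#' @export
summarizeStability <- function(table, truth = integer(0), threshold = 0L) {
  stopifnot(is(table, "StabilityTable"))
  threshold <- checkCount(threshold, "threshold", min = 0L)
  if (threshold > table@nReps) {
    stop("'threshold' cannot exceed the number of repetitions", call. = FALSE)
  }
  truth <- as.integer(truth)
  if (length(truth) && !all(truth %in% table@regionIds)) {
    stop("'truth' contains unknown region ids", call. = FALSE)
  }
  report <- list()
  metrics <- list()
  for (m in names(table@selections)) {
    S <- table@selections[[m]]
    counts <- as.integer(colSums(S))
    keep <- which(counts >= threshold & counts > 0L)
    ord <- keep[order(-counts[keep], table@regionIds[keep])]
    report[[m]] <- data.frame(region_id = table@regionIds[ord],
                              count = counts[ord], row.names = NULL)
    mt <- list(
      meanSelectedPerRep = mean(rowSums(S)),
      pairwiseJaccard = meanPairwiseJaccard(S),
      nRegionsReported = length(ord)
    )
    if (length(truth)) {
      truthCols <- match(truth, table@regionIds)
      mt$trueRegionFrequency <- setNames(counts[truthCols] / table@nReps,
                                         sprintf("region_%d", truth))
      mt$meanFalsePositives <-
        mean(rowSums(S[, -truthCols, drop = FALSE]))
    }
    metrics[[m]] <- mt
  }
  structure(list(report = report, metrics = metrics, truth = truth,
                 threshold = threshold),
            class = "stabilitySummary")
}

#' @export
print.stabilitySummary <- function(x, ...) {
  cat(sprintf("stabilitySummary (threshold %d%s)\n", x$threshold,
              if (length(x$truth)) {
                sprintf(", truth: %s", paste(x$truth, collapse = ", "))
              } else ""))
  for (m in names(x$metrics)) {
    mt <- x$metrics[[m]]
    cat(sprintf("  %-10s %d region(s) reported; %.2f selections/rep; Jaccard %.3f",
                m, mt$nRegionsReported, mt$meanSelectedPerRep,
                mt$pairwiseJaccard))
    if (!is.null(mt$trueRegionFrequency)) {
      cat(sprintf("; truth freq %s; %.2f false positives/rep",
                  paste(sprintf("%.2f", mt$trueRegionFrequency), collapse = "/"),
                  mt$meanFalsePositives))
    }
    cat("\n")
  }
  invisible(x)
}
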