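#' Mass-univariate lesion-deficit mapping
#'
#' For every atlas region, tests the Pearson correlation between its lesion
#' load and the deficit score. Two-sided p-values come from the exact null
#' t-transform `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of
#' freedom. Family-wise error is controlled by Bonferroni correction over the
#' full atlas family: a region is selected iff `p <= alpha / R`, with R the
#' total number of atlas regions (116 in the study configuration), including
#' untestable ones — never anti-conservative. Regions whose load is constant
#' in the analysed sample have an undefined correlation: they are reported
#' with `r = NA`, `p = 1`, and are never selected.
#'
#' @param loads a [LoadMatrix].
#' @param deficit a [DeficitVector] or numeric vector of scores.
#' @param alpha family-wise significance level in (0, 1).
#' @return A `data.frame` with columns `region_id`, `r`, `p`, `selected`, and
#'   attributes `alpha`, `n`, and `bonferroniDivisor`.
#' @examples
#' loads <- newLoadMatrix(matrix(runif(200), 50, 4))
#' y <- loadValues(loads)[, 2]
#' univariateMap(loads, y, alpha = 0.05)
#' @export
univariateMap <- function(loads, deficit, alpha = 0.05) {
  stopifnot(is(loads, "LoadMatrix"))
  X <- loads@values
  n <- nrow(X)
  if (n < 4L) stop("at least 4 subjects are required", call. = FALSE)
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  }
  y <- asScores(deficit, n)
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  if (sy == 0) {
    stop("deficit is constant: correlation is undefined for every region",
         call. = FALSE)
  }
  xc <- sweep(X, 2L, colMeans(X))
  sx <- sqrt(colSums(xc^2))
  r <- rep(NA_real_, ncol(X))
  ok <- sx > 0
  r[ok] <- as.vector(crossprod(xc[, ok, drop = FALSE], yc)) / (sx[ok] * sy)
  r[ok] <- pmin(1, pmax(-1, r[ok]))
  p <- rep(1, ncol(X))
  tstat <- r[ok] * sqrt((n - 2) / pmax(1 - r[ok]^2, 0))
  p[ok] <- ifelse(abs(r[ok]) >= 1, 0, 2 * pt(-abs(tstat), df = n - 2))
  R <- ncol(X)
  selected <- ok & p <= alpha / R
  out <- data.frame(region_id = loads@regionIds, r = r, p = p,
                    selected = selected, row.names = NULL)
  attr(out, "alpha") <- alpha
  attr(out, "n") <- n
  attr(out, "bonferroniDivisor") <- R
  out
}
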