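## Shared fixtures, built in code at test time.

## Small atlas + cohort used by several files; cached per session.
tinyAtlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generateAtlas(c(10, 12, 10), nRegions = 8,
                                                seed = 42)
    cache
  }
})

tinyCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- cohortSpec(nSubjects = 30, nRegions = 8, nTerritories = 3,
                         withinTerritorySpread = 0.7,
                         lesionSize = list(type = "fixed", size = 40),
                         seed = 7)
      cache <<- generateLesionMasks(tinyAtlas(), spec)
    }
    cache
  }
})

## The full-size synthetic cohort of the study configuration (180 x 116),
## shared by the acceptance tests; cached because generation takes ~1 s.
studyLoads <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      atlas <- studyAtlas()
      cohort <- generateLesionMasks(atlas, cohortSpec(seed = 1))
      cache <<- extractRegionLoads(cohort, atlas)
    }
    cache
  }
})

studyAtlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generateAtlas(c(20, 24, 20), 116, seed = 1)
    cache
  }
})

## Random lasso instance on a well-conditioned design.
randomLassoInstance <- function(n, p, seed) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * p), n, p))
  beta <- numeric(p)
  nz <- sample(p, max(1, p %/% 3))
  beta[nz] <- rnorm(length(nz))
  y <- as.vector(X %*% beta) + rnorm(n, sd = 0.5)
  y <- y - mean(y)
  list(X = X, y = y)
}

## Generic convex-optimization oracle for the lasso objective: L-BFGS-B on
## the positive/negative split b = u - v, u,v >= 0, which makes the objective
## smooth and box-constrained. Independent of any coordinate-descent code.
lassoOracle <- function(X, y, lambda) {
  n <- nrow(X); p <- ncol(X)
  fn <- function(uv) {
    b <- uv[1:p] - uv[(p + 1):(2 * p)]
    sum((y - X %*% b)^2) / (2 * n) + lambda * sum(uv)
  }
  gr <- function(uv) {
    b <- uv[1:p] - uv[(p + 1):(2 * p)]
    g <- -as.vector(crossprod(X, y - X %*% b)) / n
    c(g + lambda, -g + lambda)
  }
  fit <- optim(rep(0, 2 * p), fn, gr, method = "L-BFGS-B",
               lower = rep(0, 2 * p),
               control = list(maxit = 2000, factr = 10))
  b <- fit$par[1:p] - fit$par[(p + 1):(2 * p)]
  list(beta = b, objective = fn(fit$par))
}
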