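test_that("p-values agree with cor.test and the incomplete-beta oracle", {
  set.seed(101)
  n <- 37
  X <- matrix(runif(n * 6), n, 6)
  y <- X[, 2] + rnorm(n, sd = 0.3)
  res <- univariateMap(newLoadMatrix(X), y, alpha = 0.05)
  for (j in seq_len(6)) {
    ct <- cor.test(X[, j], y)
    expect_equal(res$r[j], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p[j], ct$p.value, tolerance = 1e-12)
    ## independent route: two-sided p = I_{v/(v+t^2)}(v/2, 1/2)
    v <- n - 2
    t2 <- res$r[j]^2 * v / (1 - res$r[j]^2)
    pBeta <- pbeta(v / (v + t2), v / 2, 0.5)
    expect_lt(abs(res$p[j] - pBeta), 1e-10)
  }
})

test_that("a perfectly correlated region is selected with p ~ 0", {
  set.seed(102)
  X <- matrix(runif(120 * 8), 120, 8)
  y <- X[, 2]
  res <- univariateMap(newLoadMatrix(X), y, alpha = 0.05)
  expect_equal(res$r[2], 1)
  expect_equal(res$p[2], 0)
  expect_true(res$selected[2])
})

test_that("selection threshold matches the inverted t quantile at alpha/R", {
  ## critical |r| for alpha = 0.05, R = 116, n = 120 from the t quantile
  n <- 120; R <- 116; alpha <- 0.05
  tCrit <- qt(1 - alpha / R / 2, df = n - 2)
  rCrit <- tCrit / sqrt(n - 2 + tCrit^2)

  ## construct columns with correlation just above / below the threshold
  set.seed(103)
  z <- scale(rnorm(n))
  makeCol <- function(rho) {
    e <- scale(resid(lm(rnorm(n) ~ z)))
    as.vector(rho * z + sqrt(1 - rho^2) * e)
  }
  X <- cbind(makeCol(rCrit * 1.02), makeCol(rCrit * 0.98),
             matrix(runif(n * (R - 2)), n, R - 2))
  X <- (X - min(X)) / (max(X) - min(X))
  res <- univariateMap(newLoadMatrix(X), as.vector(z), alpha = alpha)
  expect_true(res$selected[1])
  expect_false(res$selected[2])
  expect_equal(abs(res$r[1]) > rCrit, res$selected[1])
})

test_that("p-values are invariant to affine rescaling of y and X columns", {
  set.seed(104)
  X <- matrix(runif(50 * 5), 50, 5)
  y <- X[, 1] + rnorm(50, sd = 0.5)
  base <- univariateMap(newLoadMatrix(X), y)
  resY <- univariateMap(newLoadMatrix(X), 3 * y - 10)
  expect_equal(resY$p, base$p)
  Xr <- X
  Xr[, 3] <- X[, 3] / 4 + 0.1   # affine, stays in [0,1]
  resX <- univariateMap(newLoadMatrix(Xr), y)
  expect_equal(resX$p[3], base$p[3])
})

test_that("selection is monotone in alpha", {
  set.seed(105)
  X <- matrix(runif(60 * 12), 60, 12)
  y <- X[, 4] + rnorm(60, sd = 0.4)
  loads <- newLoadMatrix(X)
  alphas <- c(0.001, 0.01, 0.05, 0.2)
  sel <- lapply(alphas, function(a) univariateMap(loads, y, alpha = a)$selected)
  for (i in seq_len(length(alphas) - 1)) {
    expect_true(all(!sel[[i]] | sel[[i + 1]]),
                label = sprintf("selections at alpha=%g nest in alpha=%g",
                                alphas[i], alphas[i + 1]))
  }
})

test_that("constant-load regions are undefined and never selected", {
  set.seed(106)
  X <- matrix(runif(40 * 4), 40, 4)
  X[, 3] <- 0.7
  res <- univariateMap(newLoadMatrix(X), rnorm(40))
  expect_true(is.na(res$r[3]))
  expect_equal(res$p[3], 1)
  expect_false(res$selected[3])
  ## the Bonferroni divisor still counts the untestable region
  expect_identical(attr(res, "bonferroniDivisor"), 4L)
})

test_that("degenerate inputs are rejected", {
  X <- matrix(runif(40), 10, 4)
  expect_error(univariateMap(newLoadMatrix(X), rep(1, 10)), "constant")
  expect_error(univariateMap(newLoadMatrix(X[1:3, ]), rnorm(3)), "at least 4")
  expect_error(univariateMap(newLoadMatrix(X), rnorm(10), alpha = 1.5),
               "alpha")
})

test_that("Bonferroni controls the FWER under a collinear global null", {
  ## deficit independent of all loads; collinear loads from the generator
  loads <- studyLoads()
  nSim <- 400
  set.seed(107)
  anyHit <- vapply(seq_len(nSim), function(i) {
    y <- rnorm(nrow(loadValues(loads)))
    any(univariateMap(loads, y, alpha = 0.05)$selected)
  }, logical(1))
  fwer <- mean(anyHit)
  expect_lte(fwer, 0.05 + 3 * sqrt(0.05 * 0.95 / nSim))
})
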