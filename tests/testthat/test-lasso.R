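test_that("the solution is exactly zero at and above lambda_max", {
  for (s in 1:50) {
    inst <- randomLassoInstance(n = 25, p = 8, seed = s)
    lm0 <- lambdaMax(inst$X, inst$y)
    fit <- lassoFit(inst$X, inst$y, lambda = lm0)
    expect_identical(unname(fit$coefficients), rep(0, 8))
    fit2 <- lassoFit(inst$X, inst$y, lambda = lm0 * 1.5)
    expect_identical(unname(fit2$coefficients), rep(0, 8))
  }
  ## and just below lambda_max at least one coefficient activates
  inst <- randomLassoInstance(n = 25, p = 8, seed = 1)
  fit3 <- lassoFit(inst$X, inst$y, lambda = lambdaMax(inst$X, inst$y) * 0.99)
  expect_gt(sum(fit3$coefficients != 0), 0)
})

test_that("orthonormal designs reproduce the soft-threshold closed form", {
  set.seed(201)
  n <- 64; p <- 8
  ## columns with X'X/n = I
  Q <- qr.Q(qr(matrix(rnorm(n * p), n, p))) * sqrt(n)
  y <- rnorm(n, sd = 2)
  ols <- as.vector(crossprod(Q, y)) / n
  for (lambda in c(0.05, 0.2, 0.8)) {
    fit <- lassoFit(Q, y, lambda = lambda, tol = 1e-10)
    closed <- sign(ols) * pmax(abs(ols) - lambda, 0)
    expect_equal(unname(fit$coefficients), closed, tolerance = 1e-6)
  }
})

test_that("coordinate descent matches a generic convex-optimization oracle", {
  worst <- 0
  for (s in 1:50) {
    inst <- randomLassoInstance(n = 30, p = 10, seed = 100 + s)
    lambda <- 0.1 * lambdaMax(inst$X, inst$y)
    fit <- lassoFit(inst$X, inst$y, lambda = lambda)
    oracle <- lassoOracle(inst$X, inst$y, lambda)
    gap <- fit$objective - oracle$objective
    worst <- max(worst, gap)
    expect_lt(gap, 1e-4)
  }
  ## the solver should not be beaten by more than numerical noise either
  expect_gt(worst, -1e-6)
})

test_that("KKT conditions hold at the solution", {
  inst <- randomLassoInstance(n = 40, p = 12, seed = 7)
  for (lambda in c(0.02, 0.1, 0.5) * lambdaMax(inst$X, inst$y)) {
    fit <- lassoFit(inst$X, inst$y, lambda = lambda)
    expect_true(fit$converged)
    expect_true(fit$kkt$ok)
  }
})

test_that("objective is non-increasing along the warm-started path", {
  inst <- randomLassoInstance(n = 30, p = 10, seed = 5)
  lm0 <- lambdaMax(inst$X, inst$y)
  grid <- exp(seq(log(lm0), log(lm0 * 1e-3), length.out = 30))
  objs <- vapply(grid, function(l) {
    lassoFit(inst$X, inst$y, lambda = l)$objective
  }, numeric(1))
  ## at fixed y, decreasing lambda can only lower the penalized optimum
  expect_true(all(diff(objs) <= 1e-12))
  ## and the active set at lambda_max is empty
  expect_identical(sum(lassoFit(inst$X, inst$y, lm0)$coefficients != 0), 0L)
})

test_that("duplicated columns make coefficients exchangeable", {
  set.seed(202)
  n <- 50
  x <- scale(rnorm(n))
  X <- cbind(x, x, scale(matrix(rnorm(n * 3), n, 3)))
  y <- as.vector(3 * x) + rnorm(n, sd = 0.2)
  y <- y - mean(y)
  lambda <- 0.05
  fit <- lassoFit(X, y, lambda = lambda)
  b <- fit$coefficients
  total <- b[1] + b[2]
  ## redistribute the mass between the duplicates: objective is unchanged
  for (split in c(0, 0.25, 0.8, 1)) {
    b2 <- b
    b2[1] <- split * total
    b2[2] <- (1 - split) * total
    expect_lt(abs(lassoObjective(X, y, b2, lambda) - fit$objective), 1e-8)
  }
})

test_that("lassoCv recovers a perfect single predictor", {
  set.seed(203)
  X <- matrix(runif(80 * 10), 80, 10)
  y <- X[, 6]
  fit <- lassoCv(X, y, K = 5, seed = 2)
  expect_true(fit$selected[6])
  ## held-out error at small penalties is near zero
  expect_lt(min(fit$cvMse), 1e-4 * var(y))
})

test_that("lassoCv is deterministic given the seed", {
  set.seed(204)
  X <- matrix(runif(60 * 8), 60, 8)
  y <- X[, 2] + rnorm(60, sd = 0.1)
  f1 <- lassoCv(X, y, K = 5, seed = 11)
  f2 <- lassoCv(X, y, K = 5, seed = 11)
  expect_identical(f1$foldAssignment, f2$foldAssignment)
  expect_identical(f1$chosenLambda, f2$chosenLambda)
  expect_identical(f1$coefficients, f2$coefficients)
  f3 <- lassoCv(X, y, K = 5, seed = 12)
  expect_false(identical(f1$foldAssignment, f3$foldAssignment))
})

test_that("lassoCv grid, folds, and structural zeros follow the contract", {
  set.seed(205)
  X <- matrix(runif(40 * 6), 40, 6)
  X[, 4] <- 0.3  # constant column: structurally zero
  y <- X[, 1] + rnorm(40, sd = 0.2)
  fit <- lassoCv(X, y, K = 5, gridSize = 25, seed = 3)
  expect_length(fit$lambdaGrid, 25)
  expect_true(all(diff(fit$lambdaGrid) < 0))
  expect_equal(fit$lambdaGrid[25], fit$lambdaGrid[1] * 1e-3)
  expect_identical(sort(unique(fit$foldAssignment)), 1:5)
  expect_true(all(table(fit$foldAssignment) == 8))
  expect_identical(unname(fit$coefficients[4]), 0)
  expect_false(fit$selected[4])
  expect_true(fit$chosenLambda %in% fit$lambdaGrid)
})

test_that("intercept and coefficients back-transform to the original scale", {
  set.seed(206)
  X <- matrix(runif(100 * 5, 0, 1), 100, 5)
  y <- 2 + 3 * X[, 2] + rnorm(100, sd = 0.05)
  fit <- lassoCv(X, y, K = 5, seed = 4, rule = "min")
  pred <- fit$intercept + as.vector(X %*% fit$coefficients)
  expect_gt(cor(pred, y), 0.99)
  expect_equal(fit$coefficients[2], 3, tolerance = 0.15,
               ignore_attr = TRUE)
})

test_that("lassoCv agrees with glmnet on the same problem", {
  skip_if_not_installed("glmnet")
  set.seed(207)
  X <- matrix(rnorm(90 * 7), 90, 7)
  y <- X[, 1] - 2 * X[, 5] + rnorm(90, sd = 0.5)
  fit <- lassoCv(X, y, K = 5, seed = 5, rule = "min")
  g <- glmnet::glmnet(X, y, lambda = fit$chosenLambda,
                      lambda.min.ratio = 1e-3)
  expect_equal(unname(fit$coefficients),
               as.vector(g$beta), tolerance = 1e-3)
  expect_equal(fit$intercept, unname(g$a0), tolerance = 1e-3)
})

test_that("degenerate cross-validation inputs are rejected", {
  X <- matrix(runif(30), 10, 3)
  expect_error(lassoCv(X, rep(c(1, 2), 5), K = 5), "distinct responses")
  expect_error(lassoCv(matrix(0.5, 10, 3), rnorm(10), K = 5), "constant")
  expect_error(lassoFit(matrix(c(1, NA, 1, 1), 2, 2), c(1, 2), 0.1), "finite")
})
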