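makeLoads <- function(n = 40, R = 6, seed = 301) {
  set.seed(seed)
  newLoadMatrix(matrix(runif(n * R), n, R))
}

test_that("a stub mapper exercises the counting contract", {
  loads <- makeLoads()
  y <- rnorm(40)
  cfg <- stabilityConfig(nReps = 17, subsampleSize = 25, masterSeed = 3,
                         mappers = "univariate", reportThreshold = 0)
  stub <- list(stub = function(loadsSub, ySub, seed) {
    c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  })
  tab <- runStability(loads, y, cfg, mappers = stub)
  counts <- occurrenceCounts(tab, "stub")
  expect_identical(unname(counts), c(0L, 0L, 0L, 0L, 17L, 0L))
  ## counts conservation: total counts = total selections
  expect_identical(sum(counts), sum(selectionMatrix(tab, "stub")))
})

test_that("full-sample subsampling with a deterministic mapper gives 0/nReps counts", {
  loads <- makeLoads()
  d <- simulateDeficit(loads, region = 2, noiseK = 0, seed = 1)
  cfg <- stabilityConfig(nReps = 8, subsampleSize = 40, masterSeed = 5,
                         mappers = "univariate", reportThreshold = 0)
  tab <- runStability(loads, d, cfg)
  counts <- occurrenceCounts(tab, "univariate")
  expect_true(all(counts %in% c(0L, 8L)))
})

test_that("stability runs are reproducible from the master seed", {
  loads <- makeLoads()
  d <- simulateDeficit(loads, region = 3, noiseK = 0.5, seed = 2)
  cfg <- stabilityConfig(nReps = 6, subsampleSize = 30, masterSeed = 11,
                         lassoGridSize = 30, reportThreshold = 1)
  t1 <- runStability(loads, d, cfg)
  t2 <- runStability(loads, d, cfg)
  expect_identical(selectionMatrix(t1), selectionMatrix(t2))
})

test_that("a failing mapper records an empty selection, not a crash", {
  loads <- makeLoads()
  y <- rnorm(40)
  cfg <- stabilityConfig(nReps = 4, subsampleSize = 20, masterSeed = 2,
                         mappers = "univariate", reportThreshold = 0)
  bomb <- list(bomb = function(loadsSub, ySub, seed) stop("boom"),
               ok = function(loadsSub, ySub, seed) rep(TRUE, 6))
  warns <- capture_warnings(tab <- runStability(loads, y, cfg, mappers = bomb))
  expect_length(warns, 4)
  expect_match(warns, "recording an empty selection", all = TRUE)
  expect_identical(unname(occurrenceCounts(tab, "bomb")), rep(0L, 6))
  expect_identical(unname(occurrenceCounts(tab, "ok")), rep(4L, 6))
})

test_that("summarizeStability reports thresholded counts in order", {
  sel <- matrix(FALSE, 4, 5)
  sel[, 2] <- TRUE                  # count 4
  sel[1:2, 4] <- TRUE               # count 2
  sel[1:2, 5] <- TRUE               # count 2 (tie -> region 4 first)
  sel[1, 1] <- TRUE                 # count 1
  tab <- new("StabilityTable", selections = list(m = sel), regionIds = 1:5,
             nReps = 4L, subsampleSize = 3L, masterSeed = 1L)
  s0 <- summarizeStability(tab, threshold = 0)
  expect_identical(s0$report$m$region_id, c(2L, 4L, 5L, 1L))
  expect_identical(s0$report$m$count, c(4L, 2L, 2L, 1L))
  s2 <- summarizeStability(tab, threshold = 2)
  expect_identical(s2$report$m$region_id, c(2L, 4L, 5L))
  ## monotone reporting: raising the threshold never adds a region
  s3 <- summarizeStability(tab, threshold = 3)
  expect_true(all(s3$report$m$region_id %in% s2$report$m$region_id))
})

test_that("stability metrics match hand-computed values", {
  ## two repetitions selecting {1,2} and {2,3}: Jaccard = 1/3
  sel <- rbind(c(TRUE, TRUE, FALSE), c(FALSE, TRUE, TRUE))
  tab <- new("StabilityTable", selections = list(m = sel), regionIds = 1:3,
             nReps = 2L, subsampleSize = 2L, masterSeed = 1L)
  s <- summarizeStability(tab, truth = 2L, threshold = 0)
  expect_equal(s$metrics$m$pairwiseJaccard, 1 / 3)
  expect_equal(unname(s$metrics$m$trueRegionFrequency), 1.0)
  expect_equal(s$metrics$m$meanFalsePositives, 1.0)
  expect_equal(s$metrics$m$meanSelectedPerRep, 2.0)

  ## perfect-mapper bookkeeping
  perfect <- matrix(FALSE, 3, 3)
  perfect[, 2] <- TRUE
  tabP <- new("StabilityTable", selections = list(m = perfect),
              regionIds = 1:3, nReps = 3L, subsampleSize = 2L,
              masterSeed = 1L)
  sP <- summarizeStability(tabP, truth = 2L, threshold = 0)
  expect_equal(unname(sP$metrics$m$trueRegionFrequency), 1.0)
  expect_equal(sP$metrics$m$meanFalsePositives, 0.0)
  expect_equal(sP$metrics$m$pairwiseJaccard, 1.0)
})

test_that("summarize validates its inputs", {
  sel <- matrix(FALSE, 2, 3)
  tab <- new("StabilityTable", selections = list(m = sel), regionIds = 1:3,
             nReps = 2L, subsampleSize = 2L, masterSeed = 1L)
  expect_error(summarizeStability(tab, threshold = 5), "exceed")
  expect_error(summarizeStability(tab, truth = 9L), "unknown region")
})

test_that("runExperiment produces a cell per scenario with truth metrics", {
  loads <- makeLoads(n = 50)
  cfg <- stabilityConfig(nReps = 3, subsampleSize = 35, masterSeed = 4,
                         mappers = "univariate", reportThreshold = 0)
  scenarios <- list(
    list(name = "single", region = 2L, noiseK = 0.2, seed = 1L),
    list(name = "pair", weights = c(0.5, 0, 0.5, 0, 0, 0), noiseK = 1.0,
         seed = 2L))
  cells <- runExperiment(loads, scenarios, cfg)
  expect_named(cells, c("single", "pair"))
  expect_identical(cells$single$truth, 2L)
  expect_identical(cells$pair$truth, c(1L, 3L))
  expect_true(all(occurrenceCounts(cells$single$table, "univariate") <= 3L))
})

test_that("runExperiment writes byte-identical outputs on reruns", {
  loads <- makeLoads(n = 50)
  cfg <- stabilityConfig(nReps = 3, subsampleSize = 35, masterSeed = 4,
                         mappers = "univariate", reportThreshold = 0)
  scenarios <- list(list(name = "single", region = 2L, noiseK = 0.2,
                         seed = 1L))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  runExperiment(loads, scenarios, cfg, outputDir = d1, figures = FALSE)
  runExperiment(loads, scenarios, cfg, outputDir = d2, figures = FALSE)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})
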