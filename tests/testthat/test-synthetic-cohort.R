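test_that("generateAtlas tiles the foreground into contiguous labelled regions", {
  atlas <- generateAtlas(c(20, 24, 20), nRegions = 116, seed = 1)
  lab <- atlasLabels(atlas)
  expect_identical(sort(unique(as.vector(lab))), 0:116)
  expect_true(all(tabulate(lab[lab > 0], 116) >= 1))

  ## contiguity: every region is a single 6-connected component
  shape <- dim(lab)
  for (r in c(1L, 37L, 116L)) {
    vox <- which(lab == r)
    crd <- arrayInd(vox, shape)
    visited <- logical(length(vox))
    visited[1] <- TRUE
    queue <- 1L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      adj <- which(!visited &
                   rowSums(abs(sweep(crd, 2L, crd[v, ]))) == 1L)
      visited[adj] <- TRUE
      queue <- c(queue, adj)
    }
    expect_true(all(visited), label = sprintf("region %d contiguous", r))
  }
})

test_that("generateAtlas handles the degenerate single-region partition", {
  atlas <- generateAtlas(c(6, 6, 6), nRegions = 1, seed = 3)
  lab <- atlasLabels(atlas)
  expect_identical(sort(unique(as.vector(lab))), 0:1)
  ## the single region covers the whole foreground
  expect_identical(sum(lab == 1L), sum(lab > 0L))
})

test_that("generateAtlas is deterministic and errors on impossible tilings", {
  a1 <- generateAtlas(c(8, 8, 8), 20, seed = 7)
  a2 <- generateAtlas(c(8, 8, 8), 20, seed = 7)
  expect_identical(atlasLabels(a1), atlasLabels(a2))
  a3 <- generateAtlas(c(8, 8, 8), 20, seed = 8)
  expect_false(identical(atlasLabels(a1), atlasLabels(a3)))
  expect_error(generateAtlas(c(3, 3, 3), 10000), "cannot tile")
})

test_that("zero-extent lesions give all-zero masks and loads", {
  spec <- cohortSpec(nSubjects = 4, nRegions = 8, nTerritories = 3,
                     lesionSize = list(type = "fixed", size = 0), seed = 1)
  cohort <- generateLesionMasks(tinyAtlas(), spec)
  expect_true(all(vapply(lesionMasks(cohort), function(m) all(m == 0L),
                         logical(1))))
  expect_true(all(loadValues(cohort) == 0))
})

test_that("single-voxel lesions with zero spread damage exactly one region", {
  spec <- cohortSpec(nSubjects = 25, nRegions = 8, nTerritories = 3,
                     withinTerritorySpread = 0,
                     lesionSize = list(type = "fixed", size = 1), seed = 5)
  cohort <- generateLesionMasks(tinyAtlas(), spec)
  damaged <- rowSums(loadValues(cohort) > 0)
  expect_true(all(damaged == 1L))
})

test_that("lesion masks are contiguous, deterministic, and loads match masks", {
  cohort <- tinyCohort()
  cohort2 <- generateLesionMasks(tinyAtlas(), cohort@metadata$spec)
  expect_identical(lesionMasks(cohort), lesionMasks(cohort2))
  expect_identical(loadValues(cohort), loadValues(cohort2))

  ## load definition: lesioned voxels / region voxels, by direct counting
  lab <- atlasLabels(tinyAtlas())
  sizes <- tabulate(lab[lab > 0], 8)
  for (s in c(1L, 17L)) {
    m <- lesionMasks(cohort)[[s]]
    byHand <- tabulate(lab[m == 1L & lab > 0L], 8) / sizes
    expect_equal(unname(loadValues(cohort)[s, ]), byHand)
  }
})

test_that("fixed lesion extent beyond the foreground is rejected", {
  spec <- cohortSpec(nSubjects = 2, nRegions = 8, nTerritories = 2,
                     lesionSize = list(type = "fixed", size = 10^6), seed = 1)
  expect_error(generateLesionMasks(tinyAtlas(), spec), "exceeds the foreground")
})

test_that("within-territory loads correlate more strongly than between", {
  atlas <- generateAtlas(c(14, 16, 14), nRegions = 24, seed = 2)
  spec <- cohortSpec(nSubjects = 180, nRegions = 24, nTerritories = 4,
                     withinTerritorySpread = 0.8,
                     lesionSize = list(type = "fixed", size = 60), seed = 11)
  cohort <- generateLesionMasks(atlas, spec)
  terr <- cohort@metadata$territories
  C <- suppressWarnings(cor(loadValues(cohort)))
  same <- outer(terr, terr, "==") & upper.tri(C)
  diff <- outer(terr, terr, "!=") & upper.tri(C)
  expect_gt(mean(C[same], na.rm = TRUE), mean(C[diff], na.rm = TRUE))
})

test_that("within-territory correlation is monotone in the spread knob", {
  atlas <- generateAtlas(c(14, 16, 14), nRegions = 24, seed = 2)
  meanWithin <- vapply(c(0.1, 0.5, 0.9), function(sp) {
    spec <- cohortSpec(nSubjects = 500, nRegions = 24, nTerritories = 4,
                       withinTerritorySpread = sp,
                       lesionSize = list(type = "fixed", size = 60), seed = 13)
    cohort <- generateLesionMasks(atlas, spec)
    terr <- cohort@metadata$territories
    C <- suppressWarnings(cor(loadValues(cohort)))
    same <- outer(terr, terr, "==") & upper.tri(C)
    mean(C[same], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(meanWithin) > 0))
})

test_that("complexDeficitWeights samples the simplex reproducibly", {
  atlas <- tinyAtlas()
  w1 <- complexDeficitWeights(atlas, 3, seed = 3)
  w2 <- complexDeficitWeights(atlas, 3, seed = 3)
  expect_identical(w1, w2)
  expect_identical(sum(w1 > 0), 3L)
  expect_equal(sum(w1), 1)
  expect_true(all(w1 >= 0))

  ## degenerate cases: indicator vector and full simplex
  w3 <- complexDeficitWeights(atlas, 1, seed = 1)
  expect_identical(sum(w3 > 0), 1L)
  expect_equal(max(w3), 1)
  w4 <- complexDeficitWeights(atlas, 8, seed = 1)
  expect_true(all(w4 > 0))
  expect_equal(sum(w4), 1)
  expect_error(complexDeficitWeights(atlas, 9, seed = 1), "exceeds")
})
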