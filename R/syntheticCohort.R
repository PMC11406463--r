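## Synthetic cohort generator: toy atlas, territory clustering, and
## territory-biased lesion growth. The one statistical property downstream
## analyses rely on is strong positive correlation of lesion loads between
## regions sharing a territory (multicollinearity), tuned by
## withinTerritorySpread.

## Ellipsoidal "brain" foreground inscribed in the grid.
ellipsoidForeground <- function(shape) {
  ctr <- (shape + 1) / 2
  ax <- pmax(shape / 2 - 0.5, 0.5)
  d1 <- ((seq_len(shape[1]) - ctr[1]) / ax[1])^2
  d2 <- ((seq_len(shape[2]) - ctr[2]) / ax[2])^2
  d3 <- ((seq_len(shape[3]) - ctr[3]) / ax[3])^2
  array(outer(outer(d1, d2, "+"), d3, "+") <= 1, dim = shape)
}

## 6-neighbourhood of the foreground voxels: nFg x 6 matrix of foreground
## positions (0 where the neighbour is background or outside the grid).
foregroundNeighbours <- function(shape, lin) {
  nFg <- length(lin)
  pos <- integer(prod(shape))
  pos[lin] <- seq_len(nFg)
  crd <- arrayInd(lin, shape)
  nx <- shape[1]; nxy <- shape[1] * shape[2]
  steps <- c(-1L, 1L, -nx, nx, -nxy, nxy)
  dims <- c(1L, 1L, 2L, 2L, 3L, 3L)
  dirs <- c(-1L, 1L, -1L, 1L, -1L, 1L)
  nbr <- matrix(0L, nFg, 6L)
  for (d in seq_len(6L)) {
    ok <- if (dirs[d] < 0L) crd[, dims[d]] > 1L else crd[, dims[d]] < shape[dims[d]]
    nbr[ok, d] <- pos[lin[ok] + steps[d]]
  }
  nbr
}

#' Generate a toy labelled atlas volume
#'
#' Partitions an ellipsoidal foreground inside a 3-D grid into `nRegions`
#' spatially contiguous, non-overlapping regions by seeded multi-source region
#' growing (a voxel-graph Voronoi tessellation with randomized tie-breaking).
#' A stand-in for an anatomical parcellation such as the 116-region AAL atlas;
#' no anatomical semantics are implied.
#'
#' @param shape integer 3-vector of grid dimensions.
#' @param nRegions number of regions R.
#' @param seed RNG seed; the same seed reproduces the atlas bit for bit.
#' @return An [AtlasVolume] with labels in `{0} U {1..nRegions}`.
#' @examples
#' atlas <- generateAtlas(c(12, 14, 12), nRegions = 10, seed = 1)
#' table(atlasLabels(atlas))
#' @export
generateAtlas <- function(shape, nRegions, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("'shape' must be three positive voxel counts", call. = FALSE)
  }
  nRegions <- checkCount(nRegions, "nRegions")
  fg <- ellipsoidForeground(shape)
  lin <- which(fg)
  nFg <- length(lin)
  if (nRegions > nFg) {
    stop(sprintf("cannot tile %d regions into a foreground of %d voxels",
                 nRegions, nFg), call. = FALSE)
  }
  lab <- withSeed(seed, {
    lab <- integer(nFg)
    lab[sample.int(nFg, nRegions)] <- seq_len(nRegions)
    nbr <- foregroundNeighbours(shape, lin)
    while (any(lab == 0L)) {
      prev <- lab
      for (d in sample.int(6L)) {
        cand <- which(lab == 0L)
        if (!length(cand)) break
        src <- nbr[cand, d]
        has <- src > 0L
        has[has] <- prev[src[has]] > 0L
        lab[cand[has]] <- prev[src[has]]
      }
      if (identical(lab, prev)) {
        stop("foreground is disconnected; cannot complete the tessellation",
             call. = FALSE)
      }
    }
    lab
  })
  labels <- array(0L, dim = shape)
  labels[lin] <- lab
  new("AtlasVolume", labels = labels, regionIds = seq_len(nRegions))
}

#' Group atlas regions into territory-like clusters
#'
#' Assigns each region to one of `nTerritories` spatial clusters by
#' farthest-point seeding on region centroids followed by nearest-centroid
#' assignment. Emulates vascular territories: groups of adjacent regions whose
#' lesion loads will co-vary.
#'
#' @param atlas an [AtlasVolume].
#' @param nTerritories number of clusters (capped at the region count).
#' @param seed RNG seed choosing the first territory seed.
#' @return Integer vector of territory labels in 1..nTerritories, one per region.
#' @export
makeTerritories <- function(atlas, nTerritories = 12L, seed = 1L) {
  nTerritories <- checkCount(nTerritories, "nTerritories")
  R <- length(atlas@regionIds)
  nTerritories <- min(nTerritories, R)
  lin <- which(atlas@labels > 0L)
  crd <- arrayInd(lin, dim(atlas@labels))
  reg <- atlas@labels[lin]
  cent <- vapply(seq_len(3L), function(k) {
    tapply(crd[, k], reg, mean)[as.character(seq_len(R))]
  }, numeric(R))
  d2 <- as.matrix(stats::dist(cent))^2
  seeds <- integer(nTerritories)
  seeds[1] <- withSeed(seed, sample.int(R, 1L))
  if (nTerritories > 1L) {
    for (k in 2L:nTerritories) {
      dmin <- apply(d2[, seeds[seq_len(k - 1L)], drop = FALSE], 1L, min)
      dmin[seeds[seq_len(k - 1L)]] <- -Inf
      seeds[k] <- which.max(dmin)  # ties -> lowest region id
    }
  }
  apply(d2[, seeds, drop = FALSE], 1L, which.min)
}

## Draw one contiguous lesion of (at most) `extent` voxels by stochastic
## region growing on the 6-connected foreground graph. Candidates inside the
## seed voxel's region are always accepted; candidates in another region of
## the same territory with probability `spread`; candidates outside the
## territory with probability 0.1 * spread. Rejected voxels are removed from
## the frontier permanently, so growth always terminates.
growLesion <- function(extent, nbr, vreg, vterr, spread) {
  nFg <- nrow(nbr)
  if (extent <= 0L) return(integer(0))
  sv <- sample.int(nFg, 1L)
  state <- integer(nFg)               # 0 free, 1 frontier, 2 lesion, 3 rejected
  state[sv] <- 2L
  lesion <- integer(extent)
  lesion[1] <- sv
  size <- 1L
  reg0 <- vreg[sv]; terr0 <- vterr[sv]
  frontier <- integer(256L)
  flen <- 0L
  pushNbrs <- function(v) {
    for (u in nbr[v, ]) {
      if (u > 0L && state[u] == 0L) {
        state[u] <<- 1L
        flen <<- flen + 1L
        if (flen > length(frontier)) {
          frontier <<- c(frontier, integer(length(frontier)))
        }
        frontier[flen] <<- u
      }
    }
  }
  pushNbrs(sv)
  while (size < extent && flen > 0L) {
    k <- if (flen == 1L) 1L else sample.int(flen, 1L)
    v <- frontier[k]
    frontier[k] <- frontier[flen]
    flen <- flen - 1L
    p <- if (vreg[v] == reg0) 1 else if (vterr[v] == terr0) spread else 0.1 * spread
    if (stats::runif(1L) < p) {
      state[v] <- 2L
      size <- size + 1L
      lesion[size] <- v
      pushNbrs(v)
    } else {
      state[v] <- 3L
    }
  }
  lesion[seq_len(size)]
}

#' Generate a synthetic lesion cohort
#'
#' Draws one contiguous lesion per subject by seeded region growing on the
#' atlas foreground, with expansion biased towards the seed region's territory
#' so that lesion loads of regions within a territory are positively
#' correlated across subjects — the multicollinearity that makes causal
#' attribution among regions ill-posed. Returns both the binary masks and the
#' derived lesion-load matrix.
#'
#' @param atlas an [AtlasVolume].
#' @param spec a [CohortSpec]; `spec@nRegions` must equal the atlas region count.
#' @return A [LesionCohort] with masks, loads, and metadata recording the
#'   territory partition and the lesion extents drawn.
#' @examples
#' atlas <- generateAtlas(c(12, 14, 12), nRegions = 10, seed = 1)
#' spec <- cohortSpec(nSubjects = 8, nRegions = 10, nTerritories = 3,
#'                    lesionSize = list(type = "fixed", size = 25), seed = 2)
#' cohort <- generateLesionMasks(atlas, spec)
#' @export
generateLesionMasks <- function(atlas, spec) {
  stopifnot(is(atlas, "AtlasVolume"), is(spec, "CohortSpec"))
  R <- length(atlas@regionIds)
  if (spec@nRegions != R) {
    stop(sprintf("spec expects %d regions but the atlas has %d",
                 spec@nRegions, R), call. = FALSE)
  }
  territories <- if (length(spec@territoryPartition)) {
    spec@territoryPartition
  } else {
    makeTerritories(atlas, spec@nTerritories, seed = spec@seed)
  }
  shape <- dim(atlas@labels)
  lin <- which(atlas@labels > 0L)
  nFg <- length(lin)
  nbr <- foregroundNeighbours(shape, lin)
  vreg <- atlas@labels[lin]
  vterr <- territories[vreg]
  regionSize <- tabulate(vreg, nbins = R)

  ls <- spec@lesionSize
  if (ls$type == "fixed" && ls$size > nFg) {
    stop(sprintf("fixed lesion extent (%d voxels) exceeds the foreground (%d voxels)",
                 as.integer(ls$size), nFg), call. = FALSE)
  }
  n <- spec@nSubjects
  out <- withSeed(spec@seed, {
    extents <- if (ls$type == "fixed") {
      rep(as.integer(ls$size), n)
    } else {
      pmin(as.integer(round(rlnorm(n, meanlog = log(ls$medianVoxels),
                                   sdlog = ls$sdlog))), nFg)
    }
    masks <- vector("list", n)
    loads <- matrix(0, n, R)
    for (s in seq_len(n)) {
      les <- growLesion(extents[s], nbr, vreg, vterr,
                        spec@withinTerritorySpread)
      m <- array(0L, dim = shape)
      if (length(les)) m[lin[les]] <- 1L
      masks[[s]] <- m
      loads[s, ] <- tabulate(vreg[les], nbins = R) / regionSize
    }
    list(masks = masks, loads = loads, extents = extents)
  })
  ids <- sprintf("S%03d", seq_len(n))
  dimnames(out$loads) <- list(ids, sprintf("region_%d", atlas@regionIds))
  new("LesionCohort", subjectIds = ids, masks = out$masks, loads = out$loads,
      metadata = list(spec = spec, territories = territories,
                      extents = out$extents))
}

#' Draw a sparse weight vector for a multi-region ("complex") deficit
#'
#' Samples `nContributing` regions without replacement and assigns them
#' positive weights summing to 1 (normalized exponential draws, i.e. uniform
#' on the simplex). With `nContributing = 1` this reduces to the
#' single-region ground truth.
#'
#' @param atlas an [AtlasVolume] (defines the region set).
#' @param nContributing number of regions with non-zero weight, in 1..R.
#' @param seed RNG seed.
#' @return Numeric weight vector of length R, named `region_<id>`.
#' @export
complexDeficitWeights <- function(atlas, nContributing, seed = 1L) {
  R <- length(atlas@regionIds)
  nContributing <- checkCount(nContributing, "nContributing")
  if (nContributing > R) {
    stop(sprintf("nContributing (%d) exceeds the region count (%d)",
                 nContributing, R), call. = FALSE)
  }
  w <- withSeed(seed, {
    idx <- sample.int(R, nContributing)
    raw <- stats::rexp(nContributing)
    v <- numeric(R)
    v[idx] <- raw / sum(raw)
    v
  })
  setNames(w, sprintf("region_%d", atlas@regionIds))
}
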