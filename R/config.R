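## Experiment configuration: YAML/JSON schema with full defaulting, unknown-key
## rejection, manifest writing, and the end-to-end driver.

configDefaults <- function() {
  list(
    cohort = list(
      shape = c(20L, 24L, 20L),
      n_subjects = 180L,
      n_regions = 116L,
      n_territories = 12L,
      within_territory_spread = 0.8,
      lesion_size = list(type = "lognormal", median_voxels = 150,
                         sdlog = 0.7),
      seed = 1L,
      atlas_path = NULL,
      mask_paths = NULL
    ),
    scenarios = NULL,  # NULL -> the default 2-region x 2-noise grid
    stability = list(
      n_reps = 100L,
      subsample_size = 120L,
      mappers = c("univariate", "lasso"),
      report_threshold = 10L,
      master_seed = 1L,
      alpha = 0.05,
      lasso = list(folds = 5L, grid_size = 100L, rule = "1se")
    ),
    output_dir = "lesionstab-output",
    log_level = "info"
  )
}

rejectUnknown <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop(sprintf("unknown config key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
}

## 'lesion_size' is replaced wholesale (its keys depend on its type);
## everything else with named-list defaults merges recursively.
mergeDefaults <- function(user, defaults, where) {
  rejectUnknown(user, names(defaults), where)
  out <- defaults
  for (k in names(user)) {
    if (k == "lesion_size") {
      out[[k]] <- user[[k]]
    } else if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(user[[k]])) {
      out[[k]] <- mergeDefaults(user[[k]], defaults[[k]],
                                paste(where, k, sep = "$"))
    } else {
      out[[k]] <- user[[k]]
    }
  }
  out
}

#' Validate an experiment configuration
#'
#' Reads a YAML (or JSON) configuration, fills every missing field with the
#' study defaults (180 subjects, 116 regions, 100 repetitions of 120 subjects,
#' 5-fold lasso cross-validation, noise multipliers 0.2 and 1.0), rejects
#' unknown keys with field-level messages, canonicalizes types, and
#' cross-checks fields. A manifest written by [writeManifest()] re-validates
#' to an identical configuration.
#'
#' @param x path to a YAML/JSON file, or an already-parsed list.
#' @return A fully-defaulted list of class `"ExperimentConfig"`.
#' @examples
#' cfg <- validateConfig(list(stability = list(n_reps = 10)))
#' cfg$stability$n_reps
#' @export
validateConfig <- function(x) {
  user <- if (is.character(x)) {
    if (!file.exists(x)) stop(sprintf("config file '%s' not found", x),
                              call. = FALSE)
    yaml::read_yaml(x)
  } else if (is.list(x)) x else {
    stop("'x' must be a file path or a list", call. = FALSE)
  }
  if (is.null(user)) user <- list()
  ## accept a manifest (config nested under 'config')
  if (!is.null(user$config)) user <- user$config

  cfg <- mergeDefaults(user, configDefaults(), "config")

  co <- cfg$cohort
  co$shape <- vapply(co$shape, checkCount, integer(1), name = "cohort$shape")
  if (length(co$shape) != 3L) {
    stop("cohort$shape must have three entries", call. = FALSE)
  }
  co$n_subjects <- checkCount(co$n_subjects, "cohort$n_subjects")
  co$n_regions <- checkCount(co$n_regions, "cohort$n_regions")
  co$n_territories <- checkCount(co$n_territories, "cohort$n_territories")
  co$within_territory_spread <- checkProb(co$within_territory_spread,
                                          "cohort$within_territory_spread")
  ls <- co$lesion_size
  if (!is.list(ls) || is.null(ls$type)) {
    stop("cohort$lesion_size must be a list with a 'type'", call. = FALSE)
  }
  if (identical(ls$type, "fixed")) {
    rejectUnknown(ls, c("type", "size"), "cohort$lesion_size")
    ls$size <- checkCount(ls$size, "cohort$lesion_size$size", min = 0L)
  } else if (identical(ls$type, "lognormal")) {
    rejectUnknown(ls, c("type", "median_voxels", "sdlog"),
                  "cohort$lesion_size")
    ls$median_voxels <- as.numeric(ls$median_voxels)
    ls$sdlog <- as.numeric(ls$sdlog)
    if (!is.finite(ls$median_voxels) || ls$median_voxels <= 0 ||
        !is.finite(ls$sdlog) || ls$sdlog < 0) {
      stop("cohort$lesion_size: median_voxels must be > 0 and sdlog >= 0",
           call. = FALSE)
    }
  } else {
    stop("cohort$lesion_size$type must be 'fixed' or 'lognormal'",
         call. = FALSE)
  }
  co$lesion_size <- ls
  co$seed <- checkSeed(co$seed)
  if (!is.null(co$atlas_path)) co$atlas_path <- as.character(co$atlas_path)
  if (!is.null(co$mask_paths)) co$mask_paths <- as.character(co$mask_paths)
  ## canonical form carries no NULL entries (YAML round trips drop them)
  co <- co[!vapply(co, is.null, logical(1))]
  cfg$cohort <- co

  if (is.null(cfg$scenarios)) {
    cfg$scenarios <- lapply(defaultScenarioGrid(), function(sc) {
      list(name = sc$name, region = sc$region, noise_k = sc$noiseK,
           seed = sc$seed)
    })
  }
  cfg$scenarios <- lapply(seq_along(cfg$scenarios), function(i) {
    sc <- cfg$scenarios[[i]]
    where <- sprintf("scenarios[[%d]]", i)
    rejectUnknown(sc, c("name", "region", "n_contributing", "weights",
                        "noise_k", "seed"), where)
    if (is.null(sc$name)) stop(sprintf("%s needs a 'name'", where),
                               call. = FALSE)
    sc$name <- as.character(sc$name)
    targets <- c(!is.null(sc$region), !is.null(sc$n_contributing),
                 !is.null(sc$weights))
    if (sum(targets) != 1L) {
      stop(sprintf("%s must set exactly one of region / n_contributing / weights",
                   where), call. = FALSE)
    }
    if (!is.null(sc$region)) {
      sc$region <- checkCount(sc$region, paste0(where, "$region"))
      if (sc$region > cfg$cohort$n_regions) {
        stop(sprintf("%s$region exceeds cohort$n_regions", where),
             call. = FALSE)
      }
    }
    if (!is.null(sc$n_contributing)) {
      sc$n_contributing <- checkCount(sc$n_contributing,
                                      paste0(where, "$n_contributing"))
      if (sc$n_contributing > cfg$cohort$n_regions) {
        stop(sprintf("%s$n_contributing exceeds cohort$n_regions", where),
             call. = FALSE)
      }
    }
    if (!is.null(sc$weights)) {
      sc$weights <- as.numeric(sc$weights)
      if (length(sc$weights) != cfg$cohort$n_regions ||
          any(!is.finite(sc$weights)) || any(sc$weights < 0)) {
        stop(sprintf("%s$weights must be %d non-negative numbers", where,
                     cfg$cohort$n_regions), call. = FALSE)
      }
    }
    sc$noise_k <- as.numeric(sc$noise_k %||% 0)
    if (!is.finite(sc$noise_k) || sc$noise_k < 0) {
      stop(sprintf("%s$noise_k must be non-negative", where), call. = FALSE)
    }
    sc$seed <- checkSeed(sc$seed %||% 1L)
    sc
  })
  if (anyDuplicated(vapply(cfg$scenarios, `[[`, character(1), "name"))) {
    stop("scenario names must be unique", call. = FALSE)
  }

  st <- cfg$stability
  st$n_reps <- checkCount(st$n_reps, "stability$n_reps")
  st$subsample_size <- checkCount(st$subsample_size,
                                  "stability$subsample_size")
  if (st$subsample_size > cfg$cohort$n_subjects) {
    stop("stability$subsample_size exceeds cohort$n_subjects", call. = FALSE)
  }
  st$mappers <- as.character(st$mappers)
  if (!length(st$mappers) || !all(st$mappers %in% c("univariate", "lasso"))) {
    stop("stability$mappers must be a non-empty subset of {univariate, lasso}",
         call. = FALSE)
  }
  st$report_threshold <- checkCount(st$report_threshold,
                                    "stability$report_threshold", min = 0L)
  if (st$report_threshold > st$n_reps) {
    stop("stability$report_threshold exceeds stability$n_reps", call. = FALSE)
  }
  st$master_seed <- checkSeed(st$master_seed)
  st$alpha <- as.numeric(st$alpha)
  if (!is.finite(st$alpha) || st$alpha <= 0 || st$alpha >= 1) {
    stop("stability$alpha must lie in (0, 1)", call. = FALSE)
  }
  st$lasso$folds <- checkCount(st$lasso$folds, "stability$lasso$folds",
                               min = 2L)
  st$lasso$grid_size <- checkCount(st$lasso$grid_size,
                                   "stability$lasso$grid_size", min = 2L)
  st$lasso$rule <- as.character(st$lasso$rule)
  if (!st$lasso$rule %in% c("min", "1se")) {
    stop("stability$lasso$rule must be 'min' or '1se'", call. = FALSE)
  }
  cfg$stability <- st

  cfg$output_dir <- as.character(cfg$output_dir)
  cfg$log_level <- as.character(cfg$log_level)
  if (!cfg$log_level %in% c("quiet", "info", "debug")) {
    stop("log_level must be one of quiet/info/debug", call. = FALSE)
  }
  structure(cfg, class = "ExperimentConfig")
}

#' Write a run manifest
#'
#' Records the fully-defaulted configuration together with the package name
#' and version; [validateConfig()] on the manifest reproduces the identical
#' configuration, making every run reproducible bit for bit.
#'
#' @param config an `"ExperimentConfig"` (see [validateConfig()]).
#' @param path output YAML path.
#' @return The path, invisibly.
#' @export
writeManifest <- function(config, path) {
  stopifnot(inherits(config, "ExperimentConfig"))
  yaml::write_yaml(list(package = "lesionstab",
                        version = as.character(packageVersion("lesionstab")),
                        config = unclass(config)),
                   path)
  invisible(path)
}

#' Run the full experiment from a configuration
#'
#' The end-to-end driver: validates the configuration, builds the cohort
#' (synthetic generation, or mask/atlas files when paths are configured),
#' extracts region loads, resolves every scenario's ground truth, runs the
#' stability pipeline for each scenario, writes all outputs and the run
#' manifest under `output_dir`.
#'
#' @param x a config path or list accepted by [validateConfig()].
#' @param outputDir overrides the configured `output_dir`; `NULL` keeps it.
#' @param figures write PNG bar charts alongside the CSV/JSON outputs.
#' @return Invisibly, a list with `config`, `loads`, and `cells` (the
#'   [runExperiment()] result).
#' @export
runExperimentFromConfig <- function(x, outputDir = NULL, figures = TRUE) {
  cfg <- validateConfig(x)
  outDir <- outputDir %||% cfg$output_dir
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  info <- function(fmt, ...) {
    if (cfg$log_level != "quiet") message(sprintf(fmt, ...))
  }

  co <- cfg$cohort
  if (!is.null(co$atlas_path) && !is.null(co$mask_paths)) {
    info("reading %d masks + atlas from disk", length(co$mask_paths))
    disk <- loadCohortFromDisk(co$mask_paths, co$atlas_path)
    atlas <- disk$atlas
    loads <- extractRegionLoads(disk$cohort, atlas)
  } else {
    info("generating synthetic cohort: %d subjects, %d regions",
         co$n_subjects, co$n_regions)
    atlas <- generateAtlas(co$shape, co$n_regions, seed = co$seed)
    ls <- if (co$lesion_size$type == "fixed") {
      list(type = "fixed", size = co$lesion_size$size)
    } else {
      list(type = "lognormal", medianVoxels = co$lesion_size$median_voxels,
           sdlog = co$lesion_size$sdlog)
    }
    spec <- cohortSpec(nSubjects = co$n_subjects, nRegions = co$n_regions,
                       nTerritories = co$n_territories,
                       withinTerritorySpread = co$within_territory_spread,
                       lesionSize = ls, seed = co$seed)
    cohort <- generateLesionMasks(atlas, spec)
    loads <- extractRegionLoads(cohort, atlas)
  }
  writeLoadMatrixCsv(loads, file.path(outDir, "load_matrix.csv"))

  scenarios <- lapply(cfg$scenarios, function(sc) {
    out <- list(name = sc$name, noiseK = sc$noise_k, seed = sc$seed)
    if (!is.null(sc$region)) {
      out$region <- sc$region
    } else if (!is.null(sc$n_contributing)) {
      out$weights <- complexDeficitWeights(atlas, sc$n_contributing,
                                           seed = sc$seed)
    } else {
      out$weights <- sc$weights
    }
    out
  })

  st <- cfg$stability
  config <- stabilityConfig(nReps = st$n_reps,
                            subsampleSize = st$subsample_size,
                            mappers = st$mappers,
                            reportThreshold = st$report_threshold,
                            masterSeed = st$master_seed,
                            alpha = st$alpha,
                            lassoFolds = st$lasso$folds,
                            lassoGridSize = st$lasso$grid_size,
                            lassoRule = st$lasso$rule)
  info("running %d scenario(s): %d reps of %d subjects",
       length(scenarios), st$n_reps, st$subsample_size)
  cells <- runExperiment(loads, scenarios, config, outputDir = outDir,
                         figures = figures)
  writeManifest(cfg, file.path(outDir, "manifest.yaml"))
  info("outputs written to %s", outDir)
  invisible(list(config = cfg, loads = loads, cells = cells))
}
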