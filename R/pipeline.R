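#' Run the full synthetic-to-prediction pipeline
#'
#' Chains the package stages in dependency order — simulate a reference and
#' cohort, annotate the cohort against the reference, engineer per-cell-type
#' features, run the repeated survival-prediction protocol — and writes all
#' artifacts plus a manifest to an output directory. Every stochastic stage
#' derives its seed from the single global seed, so any stage is
#' reproducible in isolation and a rerun with the same configuration
#' reproduces the outputs exactly.
#'
#' @param config a named list (or path to a YAML/JSON file) with optional
#'   blocks \code{simulate} (arguments to [syntheticSpec()]),
#'   \code{annotate} (grid size, threshold), \code{features}
#'   (\code{mode} = \code{"median"}/\code{"dremi"}, \code{cellTypes},
#'   \code{minCells}), \code{predict} (\code{algorithm}, \code{nRepeats},
#'   \code{testFrac}, \code{smoteRatio}, \code{depthGrid},
#'   \code{nrounds}), and a global \code{seed}.
#' @param outDir output directory (created if needed).
#' @return the manifest, invisibly: a list describing every file written
#'   with the stage parameters that produced it.
#' @export
runPipeline <- function(config = list(), outDir) {
  if (is.character(config)) {
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(config)
              else if (ext == "json")
                jsonlite::read_json(config, simplifyVector = TRUE)
              else stop("config must be a YAML or JSON file or a list")
  }
  if (!is.list(config))
    stop("config must be a list")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  manifest <- list(seed = seed, stages = list(), files = list())
  record <- function(stage, file, params) {
    manifest$files[[file]] <<- list(stage = stage, params = params)
  }

  simArgs <- config$simulate %||% list()
  simArgs$seed <- deriveSeed(seed, 100L)
  spec <- do.call(syntheticSpec, simArgs)
  ref <- generateReference(spec)
  cohort <- generateCohort(spec)
  writeExpression(ref@expression, file.path(outDir, "reference.csv"))
  writeExpression(cohort$expression, file.path(outDir, "cohort_cells.csv"))
  utils::write.csv(cohort$survival, file.path(outDir, "clinical.csv"),
                   row.names = FALSE)
  jsonlite::write_json(truthTable(spec), file.path(outDir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  record("simulate", "reference.csv", simArgs)
  record("simulate", "cohort_cells.csv", simArgs)
  record("simulate", "clinical.csv", simArgs)
  record("simulate", "truth.json", simArgs)

  annArgs <- config$annotate %||% list()
  ann <- annotateCells(cohort$expression, ref,
                       gridRows = annArgs$gridRows %||% 10L,
                       gridCols = annArgs$gridCols %||% 10L,
                       threshold = annArgs$threshold,
                       seed = deriveSeed(seed, 200L))
  annotated <- cohort$expression
  annotated@cellLabels <- cellLabels(ann)
  utils::write.csv(
    data.frame(cell = seq_along(cellLabels(ann)),
               cluster = ann@clusterIds,
               label = cellLabels(ann)),
    file.path(outDir, "labels.csv"), row.names = FALSE)
  record("annotate", "labels.csv",
         list(gridRows = annArgs$gridRows %||% 10L,
              gridCols = annArgs$gridCols %||% 10L))

  featArgs <- config$features %||% list()
  mode <- featArgs$mode %||% "median"
  cellTypes <- featArgs$cellTypes %||% spec$cellTypes
  params <- dremiParams(minCells = featArgs$minCells %||% 200L)
  featuresList <- list()
  for (ct in cellTypes) {
    f <- if (mode == "dremi")
      dremiPairFeatures(annotated, ct, spec$signalingMarkers, params)
    else
      medianFeatures(annotated, ct, spec$signalingMarkers)
    featuresList[[ct]] <- f
    fn <- paste0("features_", gsub("[^A-Za-z0-9]", "_", ct), ".csv")
    utils::write.csv(
      data.frame(sample_id = rownames(f@values), f@values,
                 check.names = FALSE),
      file.path(outDir, fn), row.names = FALSE)
    record("features", fn, list(mode = mode, cellType = ct))
  }

  predArgs <- config$predict %||% list()
  labels <- stats::setNames(cohort$survival$group,
                            cohort$survival$sample_id)
  fit <- runCellTypeModels(
    featuresList, labels,
    nRepeats = predArgs$nRepeats %||% 100L,
    testFrac = predArgs$testFrac %||% 0.2,
    algorithm = predArgs$algorithm %||% "xgboost",
    smoteRatio = predArgs$smoteRatio,
    depthGrid = predArgs$depthGrid %||% defaultDepthGrid(),
    nrounds = predArgs$nrounds %||% 100L,
    seed = deriveSeed(seed, 300L))
  report <- list(
    classifiersTrained = fit$classifiersTrained,
    meanMetrics = fit$meanMetrics,
    importance = lapply(fit$perCellType, function(r)
      if (!is.null(r$models))
        utils::head(aggregateImportance(r$models, r$featureNames), 20)))
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  record("predict", "report.json",
         list(nRepeats = predArgs$nRepeats %||% 100L,
              algorithm = predArgs$algorithm %||% "xgboost"))

  manifest$stages <- list(simulate = TRUE, annotate = TRUE,
                          features = mode, predict = TRUE)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
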