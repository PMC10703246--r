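#' End-to-end pipeline configuration
#'
#' One flat record driving the command-level operations: file locations,
#' the two-resolution protocol (focus finding at 256 px, counting at
#' 1024 px at native scale), counting parameters, training and simulation
#' settings, and the seed. `meshMode` switches the default intensity
#' threshold from 55 to 30 unless a threshold is given explicitly. The
#' effective configuration is echoed as JSON next to every output so runs
#' are comparable: counts are only meaningful under constant imaging and
#' processing parameters.
#'
#' @param scanPath HDF5 scan path.
#' @param truthPath truth JSON sidecar path.
#' @param modelDir directory for model checkpoints.
#' @param outDir directory for counting/statistics outputs.
#' @param focusResolution,countingResolution working resolutions.
#' @param meshMode mesh-insert plates flag.
#' @param intensityThreshold optional explicit threshold override.
#' @param sim a [simConfig()] list.
#' @param train a [trainConfig()] list.
#' @param counting optional explicit [countParams()] list.
#' @param seed integer seed.
#' @return config list.
#' @export
pipelineConfig <- function(scanPath = "plate.h5",
                           truthPath = "plate_truth.json",
                           modelDir = "models", outDir = "out",
                           focusResolution = 256L,
                           countingResolution = 1024L, meshMode = FALSE,
                           intensityThreshold = NULL,
                           sim = simConfig(), train = trainConfig(),
                           counting = NULL, seed = 1L) {
  okRes <- c(64L, 128L, 256L, 512L, 1024L)
  focusResolution <- as.integer(focusResolution)
  countingResolution <- as.integer(countingResolution)
  if (!focusResolution %in% okRes || !countingResolution %in% okRes)
    stop("resolutions must be in {64, 128, 256, 512, 1024}")
  if (is.null(counting))
    counting <- countParams(intensityThreshold = intensityThreshold,
                            countingResolution = countingResolution,
                            meshMode = meshMode)
  list(scanPath = scanPath, truthPath = truthPath, modelDir = modelDir,
       outDir = outDir, focusResolution = focusResolution,
       countingResolution = countingResolution, meshMode = meshMode,
       sim = sim, train = train, counting = counting,
       seed = as.integer(seed))
}

.echoConfig <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(config, file.path(dir, "effective_config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
}

#' Simulate a plate and write scan + truth files
#'
#' @param config a [pipelineConfig()] list.
#' @param force overwrite existing outputs.
#' @return invisibly, list(scanPath, truthPath).
#' @export
cmdSimulate <- function(config = pipelineConfig(), force = FALSE) {
  for (p in c(config$scanPath, config$truthPath))
    if (file.exists(p) && !force)
      stop(sprintf("output exists (use force = TRUE): %s", p))
  sim <- config$sim
  sim$seed <- config$seed
  res <- generatePlate(sim)
  dir <- dirname(config$scanPath)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeScan(res$scan, config$scanPath)
  writeTruth(res$truth, config$truthPath)
  .echoConfig(config, dirname(config$scanPath))
  invisible(list(scanPath = config$scanPath,
                 truthPath = config$truthPath))
}

#' Train segmentation models for the requested resolutions
#'
#' Trains from VGG Image Annotator labels (`viaJson` + `imageDir`) or,
#' when those are absent, from simulator-labeled frames (scan + truth
#' files of the config). One checkpoint per resolution is written to
#' `modelDir/unet_<resolution>.rds` with a JSON config sidecar.
#'
#' @param config a [pipelineConfig()] list.
#' @param resolutions integer vector of working resolutions to train.
#' @param viaJson,imageDir optional VIA annotation source.
#' @param split train/val/test proportions.
#' @param verbose per-epoch logging.
#' @return invisibly, named list of checkpoint paths.
#' @export
cmdTrain <- function(config = pipelineConfig(),
                     resolutions = c(config$focusResolution,
                                     config$countingResolution),
                     viaJson = NULL, imageDir = NULL,
                     split = c(0.50, 0.22, 0.28), verbose = FALSE) {
  if (!is.null(viaJson)) {
    if (is.null(imageDir)) stop("imageDir required with viaJson")
    ann <- loadViaAnnotations(viaJson, imageDir)
  } else {
    if (!file.exists(config$scanPath) || !file.exists(config$truthPath))
      stop("missing annotations: provide viaJson or simulated scan/truth")
    scan <- readScan(config$scanPath)
    truth <- readTruth(config$truthPath)
    ann <- annotationsFromTruth(scan, truth)
  }
  ann <- splitAnnotations(ann, split, seed = config$seed)
  if (!dir.exists(config$modelDir))
    dir.create(config$modelDir, recursive = TRUE)
  paths <- list()
  for (res in unique(as.integer(resolutions))) {
    tc <- config$train
    tc$resolution <- res
    tc$seed <- config$seed
    model <- trainSegmenter(ann, do.call(trainConfig, tc),
                            verbose = verbose)
    p <- file.path(config$modelDir, sprintf("unet_%d.rds", res))
    saveModel(model, p)
    paths[[as.character(res)]] <- p
  }
  .echoConfig(config, config$modelDir)
  invisible(paths)
}

.loadPipelineModel <- function(config, res) {
  p <- file.path(config$modelDir, sprintf("unet_%d.rds", res))
  if (!file.exists(p))
    stop(sprintf("missing model checkpoint for resolution %d: %s", res, p))
  loadModel(p)
}

#' Run the counting pipeline over a plate scan
#'
#' Reads the scan, selects best-focus frames with the focus-resolution
#' model, counts blobs with the counting-resolution model, and writes the
#' CountTable CSV (plus overlay PNGs when requested). Logs one line per
#' well and a summary of wells counted/discarded.
#'
#' @param config a [pipelineConfig()] list.
#' @param groupLabel group label for the output table.
#' @param overlays write overlay PNGs.
#' @param verbose per-well logging.
#' @return invisibly, the CountTable data.frame (also written to
#'   `outDir/counts.csv`).
#' @export
cmdCount <- function(config = pipelineConfig(), groupLabel = "",
                     overlays = FALSE, verbose = TRUE) {
  if (!file.exists(config$scanPath))
    stop(sprintf("no such file: %s", config$scanPath))
  modelFocus <- .loadPipelineModel(config, config$focusResolution)
  modelCount <- .loadPipelineModel(config, config$countingResolution)
  if (!dir.exists(config$outDir)) dir.create(config$outDir,
                                             recursive = TRUE)
  overlayDir <- NULL
  if (overlays) {
    overlayDir <- file.path(config$outDir, "overlays")
    if (!dir.exists(overlayDir)) dir.create(overlayDir)
  }
  # wells are streamed from the chunked container one at a time
  res <- countPlateFile(config$scanPath, modelFocus, modelCount,
                        config$counting, groupLabel = groupLabel,
                        overlayDir = overlayDir, verbose = verbose)
  writeCounts(res$table, file.path(config$outDir, "counts.csv"))
  .echoConfig(config, config$outDir)
  invisible(res$table)
}

#' Compare manual and algorithmic count tables
#'
#' Reads two CountTable CSVs, groups counts by `group_label`, and runs
#' [compareGroups()]. The report is written as CSV and JSON.
#'
#' @param manualCsv,algoCsv CountTable CSV paths.
#' @param outPrefix output path prefix (writes `<prefix>.csv` and
#'   `<prefix>.json`).
#' @return invisibly, the [compareGroups()] result.
#' @export
cmdCompare <- function(manualCsv, algoCsv, outPrefix = "comparison") {
  man <- readManualCounts(manualCsv)
  alg <- readManualCounts(algoCsv)
  toGroups <- function(tab) split(tab$count, tab$group_label)
  rep <- compareGroups(toGroups(man), toGroups(alg))
  dir <- dirname(outPrefix)
  if (nzchar(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(rep$groups, paste0(outPrefix, ".csv"),
                   row.names = FALSE)
  jsonlite::write_json(rep, paste0(outPrefix, ".json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(rep)
}
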