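#' Analysis report container
#'
#' @slot manifest list: configuration, seed, package version, per-stage wall
#'   times.
#' @slot tables named list of the output tables (tuning fractions, SSIMS
#'   distance statistics, latencies and group comparison, decoding time
#'   courses).
#' @export
setClass("AnalysisReport",
  representation(manifest = "list", tables = "list"))

setMethod("show", "AnalysisReport", function(object) {
  cat("AnalysisReport (seed", object@manifest$seed, ")\n tables:",
      paste(names(object@tables), collapse = ", "), "\n")
})

#' Pipeline configuration
#'
#' @param seed master seed; per-stage sub-seeds are derived from it and
#'   recorded in the manifest.
#' @param nUnits,nTrials,nPassive scenario size (see [multimodalScenario()]).
#' @param datasetPaths optional named list (\code{MFG}, \code{PCG}) of dataset
#'   directories to load instead of simulating.
#' @param scale \code{"desk"} (200 permutations, 40 ms decoding step) or
#'   \code{"full"} (10000 permutations, 20 ms step).
#' @param alpha significance level for the tuning tests.
#' @param equivalenceShift Victor-Purpura calibration, seconds.
#' @param outDir optional output directory for the CSV tables and manifest.
#' @return list with class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(seed = 1, nUnits = 40, nTrials = 72, nPassive = 144,
                           datasetPaths = NULL, scale = c("desk", "full"),
                           alpha = 0.01, equivalenceShift = 0.1,
                           outDir = NULL) {
  scale <- match.arg(scale)
  if (!is.null(datasetPaths)) {
    bad <- unlist(datasetPaths)[!dir.exists(unlist(datasetPaths))]
    if (length(bad)) stop("dataset path(s) do not exist: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(seed = as.integer(seed), nUnits = nUnits, nTrials = nTrials,
                 nPassive = nPassive, datasetPaths = datasetPaths,
                 scale = scale, alpha = alpha,
                 equivalenceShift = equivalenceShift, outDir = outDir,
                 nPerm = if (scale == "desk") 200L else 10000L,
                 decodeStep = if (scale == "desk") 0.04 else 0.02),
            class = "pipelineConfig")
}

.stageLog <- function(stage, t0, note = "") {
  message(sprintf("[%s] %.1fs %s", stage,
                  as.numeric(Sys.time()) - t0, note))
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> sliding-window tuning fractions -> Victor-Purpura /
#' SSIMS distance statistics -> onset latencies and group comparison ->
#' sliding-window decoding with permutation bands.  Deterministic given the
#' configuration seed; when \code{outDir} is set, each stage's table is also
#' written as CSV together with a JSON manifest.
#'
#' @param config a [pipelineConfig()].
#' @return an \linkS4class{AnalysisReport}.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "pipelineConfig"))
  q <- calibrateQ(config$equivalenceShift)$q
  t0 <- as.numeric(Sys.time())

  ## stage 1: data
  if (is.null(config$datasetPaths)) {
    scen <- multimodalScenario(config$seed, nUnits = config$nUnits,
                               nTrials = config$nTrials,
                               nPassive = config$nPassive)
    data <- list(MFG = scen$MFG$dataset, PCG = scen$PCG$dataset)
  } else {
    data <- lapply(config$datasetPaths, loadDataset)
  }
  data <- lapply(data, successfulTrials)
  .stageLog("data", t0, sprintf("%d+%d trials",
                                nTrials(data[[1]]), nTrials(data[[2]])))

  grid <- windowGrid(-0.3, 0.8, 0.3, config$decodeStep)
  tables <- list()

  ## stage 2: sliding-window tuning fractions (AV trials, first-cue aligned)
  tables$tuning_fractions <- do.call(rbind, lapply(names(data), function(a) {
    av <- filterTrials(data[[a]], function(tr) tr$task == "AV")
    res <- do.call(rbind, lapply(unitIds(av), function(u) rbind(
      classifyResponsive(av, u, "cue1_onset", grid, alpha = config$alpha),
      classifySelective(av, u, "cue1_onset", grid, alpha = config$alpha))))
    cbind(area = a, ensembleFractionTimecourse(res))
  }))
  .stageLog("tuning", t0)

  ## stage 3: SSIMS distance statistics (AV trials, auditory-cue epochs)
  tables$distance_stats <- do.call(rbind, lapply(names(data), function(a) {
    av <- filterTrials(data[[a]], function(tr) tr$task == "AV")
    off <- areaOffset(a)
    feats <- pairwiseFeatures(av, "cue1_onset", off, off + 0.5, q = q)
    map <- ssimsEmbed(feats, seed = config$seed)
    st <- categoryDistanceStats(map, trialTable(av)$auditory_cue)
    data.frame(area = a, category = "auditory_cue",
               within_median = st@withinMedian,
               median_normalized_between = median(st@normalizedBetween),
               kw_p = st@kwP, degenerate = st@degenerate)
  }))
  .stageLog("ssims", t0)

  ## stage 4: onset latencies (A+V trials, per audio-visual cue combination)
  lat <- lapply(names(data), function(a) {
    apv <- filterTrials(data[[a]], function(tr) tr$task == "A+V")
    do.call(rbind, lapply(unitIds(apv), function(u) {
      r <- unitLatency(apv, u, "cue_onset")
      data.frame(area = a, unit_id = u, latency_s = r$latency)
    }))
  })
  names(lat) <- names(data)
  tables$latencies <- do.call(rbind, lat)
  la <- lat[[1]]$latency_s; lb <- lat[[2]]$latency_s
  cmp <- compareLatencyDistributions(la[!is.na(la)], lb[!is.na(lb)])
  tables$group_comparison <- data.frame(
    group_a = names(data)[1], group_b = names(data)[2],
    median_diff_s = cmp$medianDifference, p = cmp$kwP)
  .stageLog("latency", t0)

  ## stage 5: decoding (MFG: auditory cue at cue1; PCG: target at cue2)
  av <- lapply(data, filterTrials, keep = function(tr) tr$task == "AV")
  dec <- list(
    MFG_auditory = slidingDecode(av$MFG, "cue1_onset", grid, "auditory_cue",
                                 nPerm = config$nPerm, seed = config$seed),
    PCG_target = slidingDecode(av$PCG, "cue2_onset", grid, "target_id",
                               nPerm = config$nPerm, seed = config$seed))
  tables$decoding <- do.call(rbind, lapply(names(dec), function(nm)
    cbind(analysis = nm, decodingTable(dec[[nm]]))))
  .stageLog("decoding", t0)

  manifest <- list(seed = config$seed,
                   scale = config$scale, nPerm = config$nPerm,
                   nUnits = config$nUnits, nTrials = config$nTrials,
                   q = q, alpha = config$alpha,
                   package_version = as.character(utils::packageVersion("planspike")),
                   wall_time_s = as.numeric(Sys.time()) - t0)
  report <- new("AnalysisReport", manifest = manifest, tables = tables)
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables))
      write.csv(tables[[nm]], file.path(config$outDir, paste0(nm, ".csv")),
                row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @rdname runPipeline
#' @param object an AnalysisReport.
#' @export
setGeneric("reportTables", function(object) standardGeneric("reportTables"))
#' @rdname runPipeline
#' @export
setMethod("reportTables", "AnalysisReport", function(object) object@tables)
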