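#' @import methods
#' @importFrom stats kruskal.test median quantile rexp runif rpois sd setNames
#' @importFrom utils combn read.csv write.csv head
#' @useDynLib planspike, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## column sets of the trial table; event columns depend on the task variant
.LABEL_COLS <- c("trial_id", "session_id", "task", "auditory_cue",
                 "visual_cue", "target_id", "outcome")
.TASKS <- c("AV", "VA", "A+V", "passive")
.OUTCOMES <- c("success", "failure", "false_start")

.EVENT_COLS <- list(
  "AV"      = c("trial_start", "cue1_onset", "cue2_onset", "go_onset", "trial_end"),
  "VA"      = c("trial_start", "cue1_onset", "cue2_onset", "go_onset", "trial_end"),
  "A+V"     = c("trial_start", "cue_onset", "go_onset", "trial_end"),
  "passive" = c("trial_start", "stimulus_onset", "trial_end"))

#' EnsembleDataset: trial-aligned spike trains for one recorded ensemble
#'
#' Container for simultaneously recorded single units across trials of the
#' multi-modal cued-movement and passive-listening paradigms.  Spike times are
#' stored on the session clock; epochs relative to task events are extracted on
#' demand with [extractEpoch()], so one dataset serves analyses aligned to
#' different cues.
#'
#' @slot area character(1), one of \code{"MFG"}, \code{"PCG"}, \code{"other"} --
#'   the cortical recording site tag, which selects area-specific analysis
#'   offsets downstream.
#' @slot units character vector of unique unit identifiers.
#' @slot trials data.frame with one row per trial: identifier columns
#'   (\code{trial_id}, \code{session_id}), condition labels (\code{task},
#'   \code{auditory_cue}, \code{visual_cue}, \code{target_id}), the trial
#'   \code{outcome}, and one column per event name holding event times in
#'   seconds on the session clock (NA where the event is undefined for the
#'   task variant).
#' @slot spikes named list (by \code{trial_id}) of named lists (by
#'   \code{unit_id}) of numeric vectors of spike times, seconds, session clock,
#'   sorted non-decreasing.  Every (trial, unit) pair is present, possibly as
#'   an empty vector.
#'
#' @seealso [ensembleDataset()], [loadDataset()], [simulateEnsemble()]
#' @export
setClass("EnsembleDataset",
  representation(area = "character", units = "character",
                 trials = "data.frame", spikes = "list"))

setValidity("EnsembleDataset", function(object) {
  msg <- character()
  if (length(object@area) != 1L || !object@area %in% c("MFG", "PCG", "other"))
    msg <- c(msg, "area must be one of 'MFG', 'PCG', 'other'")
  if (anyDuplicated(object@units))
    msg <- c(msg, "unit ids must be unique")
  tr <- object@trials
  missing_cols <- setdiff(.LABEL_COLS, names(tr))
  if (length(missing_cols))
    return(paste("trials table missing columns:",
                 paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(tr$trial_id))
    msg <- c(msg, "trial ids must be unique")
  if (!all(tr$task %in% .TASKS))
    msg <- c(msg, paste("unknown task label(s):",
                        paste(setdiff(unique(tr$task), .TASKS), collapse = ", ")))
  if (!all(tr$outcome %in% .OUTCOMES))
    msg <- c(msg, "outcome must be success/failure/false_start")
  ## event monotonicity per task
  for (i in seq_len(nrow(tr))) {
    ev <- .EVENT_COLS[[tr$task[i]]]
    if (is.null(ev)) next
    if (!all(ev %in% names(tr))) {
      msg <- c(msg, sprintf("trial '%s': missing event column(s) %s",
                            tr$trial_id[i],
                            paste(setdiff(ev, names(tr)), collapse = ", ")))
      next
    }
    times <- as.numeric(tr[i, ev])
    if (anyNA(times) || any(!is.finite(times)))
      msg <- c(msg, sprintf("trial '%s': undefined event time among %s",
                            tr$trial_id[i], paste(ev, collapse = ", ")))
    else if (any(diff(times) <= 0))
      msg <- c(msg, sprintf("trial '%s': event times not strictly increasing",
                            tr$trial_id[i]))
    if (tr$task[i] == "passive" && !is.na(tr$target_id[i]))
      msg <- c(msg, sprintf("trial '%s': passive trials carry no target_id",
                            tr$trial_id[i]))
  }
  ## every (trial, unit) pair present, trains sorted and finite
  if (!setequal(names(object@spikes), tr$trial_id))
    msg <- c(msg, "spikes list must be keyed by exactly the trial ids")
  else for (tid in tr$trial_id) {
    st <- object@spikes[[tid]]
    if (!setequal(names(st), object@units)) {
      msg <- c(msg, sprintf("trial '%s': spike trains must cover every unit", tid))
      next
    }
    for (uid in object@units) {
      tt <- st[[uid]]
      if (length(tt) && (any(!is.finite(tt)) || is.unsorted(tt)))
        msg <- c(msg, sprintf(
          "trial '%s' unit '%s': spike times must be finite and sorted", tid, uid))
    }
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' SpikeEpochs: epoch-aligned spike trains extracted from a dataset
#'
#' @slot trains named list (trial) of named lists (unit) of numeric spike-time
#'   vectors, seconds relative to the alignment event.
#' @slot trials character, trial ids in dataset order.
#' @slot units character, unit ids.
#' @slot alignEvent character(1), the event the epoch is aligned to.
#' @slot window numeric(2), the half-open extraction interval \code{[t0, t1)}
#'   relative to the alignment event.
#' @export
setClass("SpikeEpochs",
  representation(trains = "list", trials = "character", units = "character",
                 alignEvent = "character", window = "numeric"))

#' DistanceFeatureSet: per-unit Victor-Purpura distance matrices
#'
#' Holds, for each unit, the symmetric trials x trials matrix of Victor-Purpura
#' distances between its epoch spike trains, plus their trial-wise horizontal
#' concatenation (the trials x (trials * units) feature matrix fed to the
#' SSIMS embedding).
#'
#' @slot unitMatrices named list of trials x trials symmetric matrices with
#'   zero diagonal, one per unit.
#' @slot features numeric matrix, trials x (trials * units): each trial's
#'   distance-to-every-trial rows joined across units in unit order.
#' @slot trials,units character index vectors fixing row/column order.
#' @slot q numeric(1), the temporal-precision parameter used (1/s).
#' @export
setClass("DistanceFeatureSet",
  representation(unitMatrices = "list", features = "matrix",
                 trials = "character", units = "character", q = "numeric"))

setValidity("DistanceFeatureSet", function(object) {
  n <- length(object@trials)
  for (u in names(object@unitMatrices)) {
    m <- object@unitMatrices[[u]]
    if (!all(dim(m) == n)) return(sprintf("unit '%s': matrix not %d x %d", u, n, n))
    if (max(abs(m - t(m))) > 1e-9) return(sprintf("unit '%s': matrix not symmetric", u))
    if (any(diag(m) != 0)) return(sprintf("unit '%s': nonzero diagonal", u))
    if (any(m < 0)) return(sprintf("unit '%s': negative distances", u))
  }
  if (nrow(object@features) != n)
    return("feature matrix row count must equal trial count")
  if (ncol(object@features) != n * length(object@units))
    return("feature matrix must have trials * units columns")
  TRUE
})

#' SSIMSMap: low-dimensional embedding of single-trial ensemble activity
#'
#' @slot coordinates trials x nDims matrix of embedding coordinates.
#' @slot trials character, trial ids in row order.
#' @slot settings list recording nDims, perplexity, iterations and seed.
#' @export
setClass("SSIMSMap",
  representation(coordinates = "matrix", trials = "character",
                 settings = "list"))

setValidity("SSIMSMap", function(object) {
  if (nrow(object@coordinates) != length(object@trials))
    return("coordinate rows must match trial count")
  if (any(!is.finite(object@coordinates)))
    return("coordinates must be finite")
  TRUE
})

#' CategoryDistanceStats: normalized within/between-category map distances
#'
#' Pairwise Euclidean distances among map points, split into pairs sharing a
#' category label ("within") and pairs spanning categories ("between"), both
#' normalized by the within-category median so that a between value of 1 means
#' the same separation as the typical same-category pair.
#'
#' @slot within,between raw pairwise distances.
#' @slot withinMedian numeric(1), the normalizer.
#' @slot normalizedWithin,normalizedBetween distances divided by withinMedian.
#' @slot kwP Kruskal-Wallis p-value comparing the normalized distributions.
#' @slot degenerate logical(1): TRUE when withinMedian is 0 and normalized
#'   values are undefined (set NA).
#' @export
setClass("CategoryDistanceStats",
  representation(within = "numeric", between = "numeric",
                 withinMedian = "numeric",
                 normalizedWithin = "numeric", normalizedBetween = "numeric",
                 kwP = "numeric", degenerate = "logical"))

#' DecodingResult: sliding-window cross-validated decoding time course
#'
#' @slot table data.frame with one row per window: \code{window_start},
#'   \code{accuracy}, and when a permutation band was computed,
#'   \code{band_low}, \code{band_high}.
#' @slot labelKey character(1), the trial column decoded.
#' @slot nClasses,folds,nPerm integers describing the design.
#' @slot seed integer(1), RNG seed used for folds and permutations.
#' @export
setClass("DecodingResult",
  representation(table = "data.frame", labelKey = "character",
                 nClasses = "integer", folds = "integer",
                 nPerm = "integer", seed = "integer"))

setMethod("show", "EnsembleDataset", function(object) {
  cat(sprintf("EnsembleDataset [%s]: %d units x %d trials\n",
              object@area, length(object@units), nrow(object@trials)))
  tab <- table(object@trials$task)
  cat("  tasks:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  nsp <- sum(vapply(object@spikes, function(s) sum(lengths(s)), 0))
  cat(sprintf("  %d spikes total\n", nsp))
})

setMethod("show", "DistanceFeatureSet", function(object) {
  cat(sprintf("DistanceFeatureSet: %d units, %d trials (q = %g /s)\n",
              length(object@units), length(object@trials), object@q))
  cat(sprintf("  feature matrix %d x %d\n",
              nrow(object@features), ncol(object@features)))
})

setMethod("show", "SSIMSMap", function(object) {
  s <- object@settings
  cat(sprintf("SSIMSMap: %d trials in %d dims (perplexity %g, %d iterations, seed %d)\n",
              length(object@trials), s$nDims, s$perplexity, s$iterations, s$seed))
})

setMethod("show", "CategoryDistanceStats", function(object) {
  if (object@degenerate) {
    cat("CategoryDistanceStats: DEGENERATE (within-category median = 0)\n")
    return(invisible(NULL))
  }
  cat(sprintf(
    "CategoryDistanceStats: %d within / %d between pairs\n  median normalized between = %.3f, KW p = %.3g\n",
    length(object@within), length(object@between),
    median(object@normalizedBetween), object@kwP))
})

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf("DecodingResult: '%s' (%d classes), %d windows, %d-fold CV",
              object@labelKey, object@nClasses, nrow(object@table), object@folds))
  if (object@nPerm > 0L) cat(sprintf(", %d permutations", object@nPerm))
  cat("\n")
  print(head(object@table, 3))
})
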