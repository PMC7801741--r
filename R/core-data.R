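#' Construct an EnsembleDataset
#'
#' Assembles and validates the central data container from a trial table and a
#' spike table.  Missing (trial, unit) combinations become empty spike trains;
#' unsuccessful trials are retained but flagged through their \code{outcome}
#' column (exclude them explicitly with [filterTrials()]).
#'
#' @param area recording-site tag: "MFG", "PCG" or "other".
#' @param trials data.frame of trial records (see
#'   \linkS4class{EnsembleDataset}); event times in seconds, session clock.
#' @param spikes either a data.frame with columns \code{trial_id},
#'   \code{unit_id}, \code{spike_time} (session clock, seconds), or a nested
#'   list \code{spikes[[trial_id]][[unit_id]]} of numeric vectors.
#' @param units character vector of unit ids; inferred from \code{spikes} when
#'   omitted (a data.frame \code{spikes} with no rows then requires it).
#' @return a validated \linkS4class{EnsembleDataset}.
#' @export
ensembleDataset <- function(area, trials, spikes, units = NULL) {
  trials <- as.data.frame(trials, stringsAsFactors = FALSE)
  trials$trial_id <- as.character(trials$trial_id)
  for (col in c("auditory_cue", "visual_cue", "target_id"))
    if (!col %in% names(trials)) trials[[col]] <- NA_character_
  if (is.data.frame(spikes)) {
    if (nrow(spikes)) {
      spikes$trial_id <- as.character(spikes$trial_id)
      spikes$unit_id <- as.character(spikes$unit_id)
      orphan <- setdiff(unique(spikes$trial_id), trials$trial_id)
      if (length(orphan))
        stop("spike rows reference unknown trial_id(s): ",
             paste(orphan, collapse = ", "))
    }
    if (is.null(units)) units <- sort(unique(spikes$unit_id))
    if (!length(units))
      stop("no units: supply 'units' when the spike table is empty")
    spl <- .spikeTableToList(spikes, trials$trial_id, units)
  } else {
    if (is.null(units))
      units <- unique(unlist(lapply(spikes, names), use.names = FALSE))
    spl <- lapply(setNames(trials$trial_id, trials$trial_id), function(tid) {
      st <- if (tid %in% names(spikes)) spikes[[tid]] else list()
      lapply(setNames(units, units), function(u) {
        v <- st[[u]]
        if (is.null(v)) numeric(0) else as.numeric(v)
      })
    })
  }
  new("EnsembleDataset", area = area, units = as.character(units),
      trials = trials, spikes = spl)
}

.spikeTableToList <- function(spikes, trial_ids, units) {
  empty <- lapply(setNames(units, units), function(u) numeric(0))
  out <- lapply(setNames(trial_ids, trial_ids), function(t) empty)
  if (nrow(spikes)) {
    bad <- setdiff(unique(spikes$unit_id), units)
    if (length(bad))
      stop("spike rows reference unknown unit_id(s): ", paste(bad, collapse = ", "))
    sp <- split(spikes, spikes$trial_id)
    for (tid in names(sp)) {
      byu <- split(sp[[tid]]$spike_time, sp[[tid]]$unit_id)
      for (uid in names(byu)) out[[tid]][[uid]] <- sort(as.numeric(byu[[uid]]))
    }
  }
  out
}

#' @rdname ensembleDataset
#' @param object,ds an EnsembleDataset.
#' @export
setGeneric("area", function(object) standardGeneric("area"))
#' @rdname ensembleDataset
#' @export
setMethod("area", "EnsembleDataset", function(object) object@area)

#' @rdname ensembleDataset
#' @export
setGeneric("unitIds", function(object) standardGeneric("unitIds"))
#' @rdname ensembleDataset
#' @export
setMethod("unitIds", "EnsembleDataset", function(object) object@units)

#' @rdname ensembleDataset
#' @export
setGeneric("trialTable", function(object) standardGeneric("trialTable"))
#' @rdname ensembleDataset
#' @export
setMethod("trialTable", "EnsembleDataset", function(object) object@trials)

#' @rdname ensembleDataset
#' @param trial,unit trial and unit identifiers.
#' @export
spikeTrain <- function(ds, trial, unit) ds@spikes[[as.character(trial)]][[unit]]

#' @rdname ensembleDataset
#' @export
nTrials <- function(ds) nrow(ds@trials)

#' @rdname ensembleDataset
#' @export
nUnits <- function(ds) length(ds@units)

#' Read / write a dataset directory
#'
#' The on-disk format is three UTF-8 text files in one directory:
#' \code{trials.csv} (label columns plus one column per event name, seconds),
#' \code{spikes.csv} (\code{trial_id}, \code{unit_id}, \code{spike_time}), and
#' \code{meta.yaml} (\code{area}, \code{units}, free-form provenance notes).
#' \code{saveDataset} followed by \code{loadDataset} round-trips a dataset
#' field for field.
#'
#' @param path directory to read from / write to.
#' @return \code{loadDataset}: a validated \linkS4class{EnsembleDataset};
#'   \code{saveDataset}: \code{path}, invisibly.
#' @export
loadDataset <- function(path) {
  need <- file.path(path, c("trials.csv", "spikes.csv", "meta.yaml"))
  miss <- need[!file.exists(need)]
  if (length(miss)) stop("missing dataset file(s): ", paste(miss, collapse = ", "))
  meta <- yaml::read_yaml(need[3])
  trials <- read.csv(need[1], stringsAsFactors = FALSE,
                     colClasses = c(trial_id = "character"))
  spikes <- read.csv(need[2], stringsAsFactors = FALSE,
                     colClasses = c(trial_id = "character", unit_id = "character"))
  ensembleDataset(meta$area, trials, spikes, units = as.character(meta$units))
}

#' @rdname loadDataset
#' @param ds an EnsembleDataset.
#' @export
saveDataset <- function(ds, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write.csv(ds@trials, file.path(path, "trials.csv"), row.names = FALSE, na = "")
  rows <- lapply(ds@trials$trial_id, function(tid) {
    st <- ds@spikes[[tid]]
    n <- lengths(st)
    data.frame(trial_id = rep(tid, sum(n)),
               unit_id = rep(names(st), n),
               spike_time = unlist(st, use.names = FALSE))
  })
  write.csv(do.call(rbind, rows), file.path(path, "spikes.csv"), row.names = FALSE)
  yaml::write_yaml(list(area = ds@area, units = as.list(ds@units)),
                   file.path(path, "meta.yaml"))
  invisible(path)
}

#' Filter trials by a predicate
#'
#' @param ds an EnsembleDataset.
#' @param keep a predicate: called on each trial record (one-row list of trial
#'   table columns) and returning TRUE to keep the trial.
#' @return an EnsembleDataset restricted to the matching trials (spike trains
#'   restricted accordingly).  Removing every trial raises a warning, not an
#'   error.
#' @examples
#' \dontrun{
#' ds <- filterTrials(ds, function(tr) tr$outcome == "success")
#' av <- filterTrials(ds, function(tr) tr$task == "AV")
#' }
#' @export
filterTrials <- function(ds, keep) {
  tr <- ds@trials
  sel <- vapply(seq_len(nrow(tr)),
                function(i) isTRUE(keep(as.list(tr[i, , drop = FALSE]))),
                logical(1))
  if (!any(sel)) warning("predicate removed every trial; empty dataset returned")
  new("EnsembleDataset", area = ds@area, units = ds@units,
      trials = tr[sel, , drop = FALSE],
      spikes = ds@spikes[tr$trial_id[sel]])
}

#' Keep only successful trials
#' @param ds an EnsembleDataset.
#' @export
successfulTrials <- function(ds) filterTrials(ds, function(tr) tr$outcome == "success")

#' Extract an event-aligned epoch
#'
#' Re-expresses each spike train relative to a named trial event and keeps the
#' spikes falling in the half-open interval \code{[t0, t1)} around it.
#'
#' @param ds an EnsembleDataset.
#' @param alignEvent event column name, defined for every trial in \code{ds}.
#' @param t0,t1 epoch bounds in seconds relative to the event, \code{t0 < t1};
#'   negative values reach before the event.
#' @return a \linkS4class{SpikeEpochs} object.
#' @export
extractEpoch <- function(ds, alignEvent, t0, t1) {
  stopifnot(t0 < t1)
  tr <- ds@trials
  if (!alignEvent %in% names(tr))
    stop("unknown event: ", alignEvent)
  at <- tr[[alignEvent]]
  bad <- tr$trial_id[is.na(at)]
  if (length(bad))
    stop("event '", alignEvent, "' undefined for trial(s): ",
         paste(bad, collapse = ", "))
  trains <- lapply(seq_len(nrow(tr)), function(i) {
    a <- at[i]
    lapply(ds@spikes[[tr$trial_id[i]]], function(s) {
      rel <- s - a
      rel[rel >= t0 & rel < t1]
    })
  })
  names(trains) <- tr$trial_id
  new("SpikeEpochs", trains = trains, trials = tr$trial_id, units = ds@units,
      alignEvent = alignEvent, window = c(t0, t1))
}

#' Spike count and rate in a window
#'
#' Windows are half-open \code{[start, start + width)}: a spike exactly at the
#' right edge belongs to the next window, so counts over a partition of an
#' interval add up exactly.
#'
#' @param train numeric vector of spike times (seconds).
#' @param start window start (seconds).
#' @param width window width (seconds), > 0.
#' @return \code{countInWindow}: integer count; \code{rateInWindow}: count /
#'   width, spikes per second.
#' @export
countInWindow <- function(train, start, width) {
  stopifnot(width > 0)
  sum(train >= start & train < start + width)
}

#' @rdname countInWindow
#' @export
rateInWindow <- function(train, start, width) countInWindow(train, start, width) / width

#' Sliding-window grids
#'
#' \code{windowGrid} validates the parameters of a sliding-window analysis;
#' \code{makeWindows} lays out the windows: starts at
#' \code{rangeStart, rangeStart + step, ...} while the whole window still fits
#' inside \code{[rangeStart, rangeEnd]}, i.e.
#' \code{floor((rangeEnd - rangeStart - width) / step) + 1} windows.
#'
#' @param rangeStart,rangeEnd analysed interval, seconds relative to the
#'   alignment event.
#' @param width window width (seconds), > 0.
#' @param step window increment (seconds), > 0.
#' @return \code{windowGrid}: a list with class \code{"windowGrid"};
#'   \code{makeWindows}: data.frame with columns \code{start}, \code{end}
#'   (\code{end = start + width}; the interval is half-open).  Empty when no
#'   window fits.
#' @examples
#' nrow(makeWindows(windowGrid(0, 0.8, 0.3, 0.02)))  # 26
#' @export
windowGrid <- function(rangeStart, rangeEnd, width, step) {
  stopifnot(is.numeric(rangeStart), is.numeric(rangeEnd),
            width > 0, step > 0, rangeEnd > rangeStart)
  structure(list(rangeStart = rangeStart, rangeEnd = rangeEnd,
                 width = width, step = step),
            class = "windowGrid")
}

#' @rdname windowGrid
#' @param grid a \code{windowGrid}.
#' @export
makeWindows <- function(grid) {
  span <- grid$rangeEnd - grid$rangeStart
  if (grid$width > span + 1e-12)
    return(data.frame(start = numeric(0), end = numeric(0)))
  n <- floor((span - grid$width) / grid$step + 1e-9) + 1
  start <- grid$rangeStart + (seq_len(n) - 1) * grid$step
  data.frame(start = start, end = start + grid$width)
}
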