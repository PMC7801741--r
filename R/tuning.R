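## Sliding-window responsive/selective classification and fixed-window aural
## encoding tests.  All comparisons are Kruskal-Wallis rank tests on per-trial
## spike counts (fixed-width windows make counts and rates equivalent for rank
## tests).

#' First informative cue event of a task variant
#' @param task task label.
#' @return event column name of the first cue (stimulus onset for passive).
#' @export
firstCueEvent <- function(task) {
  switch(task,
         "AV" = "cue1_onset", "VA" = "cue1_onset", "A+V" = "cue_onset",
         "passive" = "stimulus_onset",
         stop("unknown task: ", task))
}

## KW test robust to the zero-variance case (all counts equal in every group
## -> no evidence of difference; p = 1 by convention)
.kwP <- function(groups) {
  v <- unlist(groups, use.names = FALSE)
  if (length(unique(v)) < 2L) return(1)
  kruskal.test(groups)$p.value
}

## per-trial spike counts of one unit in a window relative to an event column
.eventCounts <- function(ds, unit, event, start, width) {
  tr <- ds@trials
  at <- tr[[event]]
  if (anyNA(at))
    stop("event '", event, "' undefined for trial(s): ",
         paste(tr$trial_id[is.na(at)], collapse = ", "))
  vapply(seq_len(nrow(tr)), function(i)
    countInWindow(ds@spikes[[tr$trial_id[i]]][[unit]], at[i] + start, width),
    numeric(1))
}

## counts aligned to each trial's auditory event
.auditoryCounts <- function(ds, unit, start, width) {
  tr <- ds@trials
  vapply(seq_len(nrow(tr)), function(i) {
    at <- tr[[auditoryAlignEvent(tr$task[i])]][i]
    countInWindow(ds@spikes[[tr$trial_id[i]]][[unit]], at + start, width)
  }, numeric(1))
}

#' Sliding-window responsiveness classification
#'
#' Tests, in each window of a sliding grid, whether a unit's per-trial firing
#' rates differ from its pre-cue baseline rates (two-group Kruskal-Wallis).
#' The baseline distribution is the per-trial rate in the
#' \code{baselineWindow} (default the 300 ms preceding the trial's first cue),
#' reused for every analysed window -- including windows aligned to later
#' cues, so that sustained delay activity counts as a response rather than
#' being absorbed into the null.
#'
#' @param ds an EnsembleDataset (a single task variant).
#' @param unit unit id.
#' @param alignEvent event column the window grid is relative to.
#' @param grid a [windowGrid()].
#' @param baselineEvent event preceding which the baseline is taken; defaults
#'   to the first cue of the dataset's (single) task.
#' @param baselineWindow numeric(2): baseline interval relative to
#'   \code{baselineEvent} (default \code{c(-0.3, 0)}).
#' @param alpha significance level (default 0.01).
#' @return data.frame: \code{unit_id}, \code{window_start}, \code{test},
#'   \code{p}, \code{significant}.
#' @export
classifyResponsive <- function(ds, unit, alignEvent, grid,
                               baselineEvent = NULL,
                               baselineWindow = c(-0.3, 0), alpha = 0.01) {
  if (nTrials(ds) < 5) stop("need at least 5 trials")
  if (is.null(baselineEvent))
    baselineEvent <- firstCueEvent(unique(ds@trials$task)[1])
  bw <- diff(baselineWindow)
  base <- .eventCounts(ds, unit, baselineEvent, baselineWindow[1], bw) / bw
  win <- makeWindows(grid)
  p <- vapply(seq_len(nrow(win)), function(k) {
    rates <- .eventCounts(ds, unit, alignEvent, win$start[k], grid$width) /
      grid$width
    .kwP(list(base, rates))
  }, numeric(1))
  data.frame(unit_id = unit, window_start = win$start, test = "responsive",
             p = p, significant = p < alpha)
}

#' Sliding-window selectivity classification
#'
#' Tests, in each window, whether a unit's per-trial rates differ across
#' condition groups (Kruskal-Wallis across the levels of \code{groupBy},
#' typically the cued target).
#'
#' @inheritParams classifyResponsive
#' @param groupBy trial column defining the condition groups (default
#'   \code{"target_id"}).
#' @return data.frame as in [classifyResponsive()] with \code{test =
#'   "selective"}.
#' @export
classifySelective <- function(ds, unit, alignEvent, grid,
                              groupBy = "target_id", alpha = 0.01) {
  labels <- as.character(ds@trials[[groupBy]])
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 condition groups")
  if (any(tab < 3))
    stop("condition group(s) with < 3 trials: ",
         paste(names(tab)[tab < 3], collapse = ", "))
  win <- makeWindows(grid)
  p <- vapply(seq_len(nrow(win)), function(k) {
    rates <- .eventCounts(ds, unit, alignEvent, win$start[k], grid$width) /
      grid$width
    .kwP(split(rates, labels))
  }, numeric(1))
  data.frame(unit_id = unit, window_start = win$start, test = "selective",
             p = p, significant = p < alpha)
}

#' Per-window fraction of responsive / selective units
#'
#' @param results data.frame row-binding the [classifyResponsive()] /
#'   [classifySelective()] outputs of all units of an ensemble (all units must
#'   share one window grid).
#' @return data.frame: \code{window_start}, \code{test}, \code{fraction},
#'   \code{n_units}.
#' @export
ensembleFractionTimecourse <- function(results) {
  agg <- aggregate(significant ~ window_start + test, data = results, FUN = mean)
  n <- aggregate(significant ~ window_start + test, data = results, FUN = length)
  data.frame(window_start = agg$window_start, test = agg$test,
             fraction = agg$significant, n_units = n$significant)
}

#' Fixed-window aural responsiveness test
#'
#' For each auditory stimulus presented in the dataset, compares per-trial
#' spike counts in a 500 ms pre-stimulus baseline window against counts in a
#' 500 ms post-stimulus window starting \code{offset} after stimulus onset
#' (200 ms for MFG-profile ensembles, 400 ms for PCG).  The unit is aurally
#' responsive if any stimulus yields Kruskal-Wallis p below the
#' Bonferroni-corrected level \code{alpha / n_stimuli}.
#'
#' @param ds an EnsembleDataset (one listening context: a task variant or
#'   passive listening).
#' @param unit unit id.
#' @param offset post-stimulus window start, seconds; default from
#'   [areaOffset()].
#' @param alpha uncorrected significance level (default 0.01).
#' @param width window width, seconds (default 0.5).
#' @return list: \code{responsive} flag, per-stimulus \code{p} values, the
#'   \code{correction} factor applied, and \code{threshold}.
#' @export
auralResponsiveness <- function(ds, unit, offset = areaOffset(area(ds)),
                                alpha = 0.01, width = 0.5) {
  stim <- as.character(ds@trials$auditory_cue)
  if (anyNA(stim)) stop("trial(s) without auditory stimulus label")
  tab <- table(stim)
  if (any(tab < 5))
    stop("stimulus with < 5 trials: ", paste(names(tab)[tab < 5], collapse = ", "))
  base <- .auditoryCounts(ds, unit, -width, width)
  post <- .auditoryCounts(ds, unit, offset, width)
  p <- vapply(names(tab), function(s) {
    sel <- stim == s
    .kwP(list(base[sel], post[sel]))
  }, numeric(1))
  k <- length(tab)
  list(responsive = any(p < alpha / k), p = p, correction = k,
       threshold = alpha / k)
}

#' Fixed-window aural selectivity test
#'
#' Kruskal-Wallis across the auditory stimuli on per-trial spike counts in the
#' fixed 500 ms response window: does the unit's evoked response discriminate
#' between the sounds presented in this context?
#'
#' @inheritParams auralResponsiveness
#' @return list: \code{selective} flag and the KW \code{p} value.
#' @export
auralSelectivity <- function(ds, unit, offset = areaOffset(area(ds)),
                             alpha = 0.01, width = 0.5) {
  stim <- as.character(ds@trials$auditory_cue)
  tab <- table(stim)
  if (length(tab) < 2) stop("need at least 2 auditory stimuli")
  if (any(tab < 3))
    stop("stimulus with < 3 trials: ", paste(names(tab)[tab < 3], collapse = ", "))
  post <- .auditoryCounts(ds, unit, offset, width)
  p <- .kwP(split(post, stim))
  list(selective = p < alpha, p = p)
}

#' Context-dependent response modulation test
#'
#' Compares a unit's stimulus-evoked spike counts for each instructional
#' auditory cue in the multi-modal task against its pooled evoked counts over
#' all passive-listening stimuli (the passive trial types are grouped because
#' passive responses do not discriminate between sounds).  The unit is
#' context-modulated if any task cue yields Kruskal-Wallis p below the
#' Bonferroni-corrected level \code{alpha / n_cues}.
#'
#' @param dsTask EnsembleDataset of multi-modal task trials.
#' @param dsPassive EnsembleDataset of passive-listening trials from the same
#'   units.
#' @param unit unit id, present in both datasets.
#' @inheritParams auralResponsiveness
#' @return list: \code{modulated} flag, per-cue \code{p} values,
#'   \code{correction}, \code{threshold}.
#' @export
contextModulation <- function(dsTask, dsPassive, unit,
                              offset = areaOffset(area(dsTask)),
                              alpha = 0.01, width = 0.5) {
  if (!unit %in% dsTask@units || !unit %in% dsPassive@units)
    stop("unit '", unit, "' must be present in both datasets")
  cues <- as.character(dsTask@trials$auditory_cue)
  evTask <- .auditoryCounts(dsTask, unit, offset, width)
  evPass <- .auditoryCounts(dsPassive, unit, offset, width)
  ucues <- sort(unique(cues))
  p <- vapply(ucues, function(cue)
    .kwP(list(evTask[cues == cue], evPass)), numeric(1))
  k <- length(ucues)
  list(modulated = any(p < alpha / k), p = p, correction = k,
       threshold = alpha / k)
}

#' @importFrom stats aggregate
NULL
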