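## Response-onset latency estimation: earliest run of consecutive 100 ms bins
## (stepped every 20 ms) whose spike-count distribution departs from the
## pooled pre-cue baseline bins.

#' Latency estimation parameters
#'
#' Defaults: baseline spike counts from the eight non-overlapping 100 ms bins
#' in the -800..0 ms pre-cue window (pooled across bins and trials); post-cue
#' counts from 100 ms bins stepped every 20 ms across 0..800 ms (activity
#' beyond 800 ms is not analysed to avoid anticipation of upcoming cues);
#' Kruskal-Wallis at alpha = 0.01; onset declared at the first run of 3
#' consecutive significant bins, reported as the midpoint of the run's first
#' bin; estimates below 40 ms are excluded.
#'
#' @param baselineRange,postRange analysed intervals, seconds relative to cue.
#' @param binWidth bin width, seconds.
#' @param step post-cue bin increment, seconds.
#' @param alpha per-bin significance level.
#' @param runLength required number of consecutive significant bins.
#' @param minLatency exclusion threshold, seconds.
#' @return list of parameters.
#' @export
latencyParams <- function(baselineRange = c(-0.8, 0), postRange = c(0, 0.8),
                          binWidth = 0.1, step = 0.02, alpha = 0.01,
                          runLength = 3, minLatency = 0.04) {
  stopifnot(binWidth > 0, step > 0, runLength >= 1, minLatency >= 0)
  list(baselineRange = baselineRange, postRange = postRange,
       binWidth = binWidth, step = step, alpha = alpha,
       runLength = runLength, minLatency = minLatency)
}

#' Response-onset latency of one unit
#'
#' Builds the pooled baseline spike-count sample (all non-overlapping
#' pre-cue bins of all trials), tests each overlapping post-cue bin against it
#' with a Kruskal-Wallis test, and reports the midpoint of the first bin of
#' the earliest run of \code{runLength} consecutive significant bins.  With
#' the default parameters estimates are quantized to the bin-midpoint grid
#' 50, 70, 90, ... ms.
#'
#' @param ds an EnsembleDataset, already restricted to the trials of one cue
#'   condition (see [unitLatency()] for the per-cue-type minimum).
#' @param unit unit id.
#' @param alignEvent event column the bins are relative to.
#' @param params a [latencyParams()] list.
#' @return list: \code{unit_id}, \code{latency} (seconds, or NA),
#'   \code{firstBin} (start of the run's first bin, or NA), \code{excluded}
#'   flag and \code{reason} ("none", "none_found", "below_minimum"), and the
#'   per-bin \code{p} values.
#' @export
onsetLatency <- function(ds, unit, alignEvent, params = latencyParams()) {
  if (nTrials(ds) < 5) stop("need at least 5 trials")
  p <- params
  ## pooled baseline: counts in each non-overlapping pre-cue bin of each trial
  bstarts <- seq(p$baselineRange[1], p$baselineRange[2] - p$binWidth,
                 by = p$binWidth)
  base <- unlist(lapply(bstarts, function(s)
    .eventCounts(ds, unit, alignEvent, s, p$binWidth)), use.names = FALSE)
  pstarts <- seq(p$postRange[1], p$postRange[2] - p$binWidth, by = p$step)
  pvals <- vapply(pstarts, function(s)
    .kwP(list(base, .eventCounts(ds, unit, alignEvent, s, p$binWidth))),
    numeric(1))
  sig <- pvals < p$alpha
  res <- list(unit_id = unit, latency = NA_real_, firstBin = NA_real_,
              excluded = FALSE, reason = "none_found", p = pvals,
              binStart = pstarts)
  r <- rle(sig)
  runEnds <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= p$runLength)
  if (!length(hit)) return(res)
  first <- runEnds[hit[1]] - r$lengths[hit[1]] + 1L
  lat <- pstarts[first] + p$binWidth / 2
  res$firstBin <- pstarts[first]
  res$latency <- lat
  res$reason <- "none"
  if (lat < p$minLatency) {
    res$excluded <- TRUE
    res$reason <- "below_minimum"
    res$latency <- NA_real_
  }
  res
}

#' Per-cue-type minimum onset latency of a unit
#'
#' Runs [onsetLatency()] separately on the trials of each cue condition (so a
#' unit responding to only a subset of cues is not averaged out) and returns
#' the shortest latency across conditions.  The conventional condition keys
#' are the two auditory cues for AV trials, the two visual cues for VA trials
#' and the four audio-visual combinations (targets) for A+V trials.
#'
#' @param ds an EnsembleDataset (one task variant).
#' @param unit unit id.
#' @param alignEvent event column the bins are relative to.
#' @param conditionKey trial column whose levels define the cue conditions;
#'   default chooses \code{auditory_cue} for AV, \code{visual_cue} for VA and
#'   \code{target_id} for A+V trials.
#' @param params a [latencyParams()] list.
#' @return list: \code{unit_id}, \code{latency} (the minimum, or NA when no
#'   condition yields one) and \code{perCondition} (named latency vector).
#' @export
unitLatency <- function(ds, unit, alignEvent, conditionKey = NULL,
                        params = latencyParams()) {
  task <- unique(ds@trials$task)[1]
  if (is.null(conditionKey))
    conditionKey <- switch(task, "AV" = "auditory_cue", "VA" = "visual_cue",
                           "A+V" = "target_id", "auditory_cue")
  labels <- as.character(ds@trials[[conditionKey]])
  per <- vapply(sort(unique(labels)), function(lab) {
    sub <- filterTrials(ds, function(tr) identical(tr[[conditionKey]], lab))
    onsetLatency(sub, unit, alignEvent, params)$latency
  }, numeric(1))
  lat <- if (all(is.na(per))) NA_real_ else min(per, na.rm = TRUE)
  list(unit_id = unit, latency = lat, perCondition = per)
}

#' Compare two latency distributions
#'
#' @param a,b numeric vectors of onset latencies (seconds), e.g. all detected
#'   MFG latencies vs all detected PCG latencies.  Positive median difference
#'   means group \code{a} responds earlier.
#' @return list: \code{medianDifference} = \code{median(b) - median(a)}
#'   (seconds) and \code{kwP}, the Kruskal-Wallis p-value.
#' @export
compareLatencyDistributions <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both latency groups must be non-empty")
  list(medianDifference = median(b) - median(a), kwP = .kwP(list(a, b)))
}
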