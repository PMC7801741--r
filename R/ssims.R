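#' SSIMS embedding of single-trial ensemble activity
#'
#' Maps trials into a low-dimensional space with t-SNE applied to the
#' concatenated per-unit Victor-Purpura distance rows (each trial is
#' represented by its vector of distances to every trial, for every unit).
#' Nearby points are trials whose ensemble spiking patterns are similar under
#' the edit-distance metric.
#'
#' @param features a \linkS4class{DistanceFeatureSet} from
#'   [pairwiseFeatures()].
#' @param nDims embedding dimensionality (default 2).
#' @param perplexity t-SNE perplexity; must be < (trials - 1) / 3.  Default
#'   NULL uses \code{min(30, floor((trials - 1) / 3))}.
#' @param iterations gradient-descent iterations (default 1000).
#' @param seed integer seed; the embedding is deterministic given it.
#' @return a \linkS4class{SSIMSMap}; the settings used are recorded in it.
#' @export
ssimsEmbed <- function(features, nDims = 2, perplexity = NULL,
                       iterations = 1000, seed = 1) {
  X <- features@features
  n <- nrow(X)
  if (n < 5) stop("need at least 5 trials to embed")
  maxPerp <- (n - 1) / 3
  if (is.null(perplexity))
    perplexity <- min(30, if (floor(maxPerp) == maxPerp) maxPerp - 1
                      else floor(maxPerp))
  if (perplexity >= maxPerp)
    stop(sprintf("perplexity %g too large for %d trials; maximum is %g",
                 perplexity, n, maxPerp - 1e-9))
  fit <- .withSeed(seed,
    Rtsne::Rtsne(X, dims = nDims, perplexity = perplexity,
                 max_iter = iterations, pca = FALSE,
                 check_duplicates = FALSE, verbose = FALSE))
  coords <- fit$Y
  rownames(coords) <- features@trials
  new("SSIMSMap", coordinates = coords, trials = features@trials,
      settings = list(nDims = nDims, perplexity = perplexity,
                      iterations = iterations, seed = seed))
}

#' @rdname ssimsEmbed
#' @param object,map an SSIMSMap.
#' @export
setGeneric("coordinates", function(object) standardGeneric("coordinates"))
#' @rdname ssimsEmbed
#' @export
setMethod("coordinates", "SSIMSMap", function(object) object@coordinates)

#' Normalized within/between-category map distances
#'
#' Splits the pairwise Euclidean distances among map points into pairs that
#' share a category label ("within") and pairs that span categories
#' ("between"), and normalizes both by the within-category median: a
#' normalized between-category value of 1 means a pair of trials from
#' different categories is as far apart as the typical pair from a common
#' category, and values above 1 mean the categories separate.  A
#' Kruskal-Wallis test compares the two normalized distributions.
#'
#' @param map an \linkS4class{SSIMSMap}, or directly a numeric coordinate
#'   matrix (rows = trials).
#' @param labels per-trial category labels (>= 2 categories, each with >= 2
#'   trials).
#' @return a \linkS4class{CategoryDistanceStats}.  When the within-category
#'   median is 0 (coincident points) the result is flagged degenerate and the
#'   normalized values and p-value are NA.
#' @export
categoryDistanceStats <- function(map, labels) {
  coords <- if (is(map, "SSIMSMap")) map@coordinates else as.matrix(map)
  labels <- as.character(labels)
  if (length(labels) != nrow(coords))
    stop("labels must have one entry per map point")
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 categories")
  if (any(tab < 2))
    stop("category with < 2 trials (no within pairs): ",
         paste(names(tab)[tab < 2], collapse = ", "))
  D <- as.matrix(stats::dist(coords))
  idx <- which(upper.tri(D), arr.ind = TRUE)
  same <- labels[idx[, 1]] == labels[idx[, 2]]
  within <- D[upper.tri(D)][same]
  between <- D[upper.tri(D)][!same]
  wm <- median(within)
  if (wm == 0)
    return(new("CategoryDistanceStats", within = within, between = between,
               withinMedian = 0, normalizedWithin = rep(NA_real_, length(within)),
               normalizedBetween = rep(NA_real_, length(between)),
               kwP = NA_real_, degenerate = TRUE))
  nw <- within / wm
  nb <- between / wm
  kw <- kruskal.test(list(nw, nb))
  new("CategoryDistanceStats", within = within, between = between,
      withinMedian = wm, normalizedWithin = nw, normalizedBetween = nb,
      kwP = kw$p.value, degenerate = FALSE)
}

#' Pool normalized distance statistics across sessions
#'
#' Each session's distances are already normalized by its own within-category
#' median (removing session-scale differences), so pooling concatenates the
#' normalized values and re-tests the pooled within vs between distributions
#' with a Kruskal-Wallis test.
#'
#' @param statsList list of \linkS4class{CategoryDistanceStats}, one per
#'   session (degenerate entries are not allowed).
#' @return a \linkS4class{CategoryDistanceStats} over the pooled normalized
#'   values (the raw slots hold the pooled normalized distances and
#'   \code{withinMedian} is 1 by construction).
#' @export
poolCategoryDistanceStats <- function(statsList) {
  if (any(vapply(statsList, slot, logical(1), "degenerate")))
    stop("cannot pool degenerate (zero within-median) session statistics")
  nw <- unlist(lapply(statsList, slot, "normalizedWithin"))
  nb <- unlist(lapply(statsList, slot, "normalizedBetween"))
  kw <- kruskal.test(list(nw, nb))
  new("CategoryDistanceStats", within = nw, between = nb, withinMedian = 1,
      normalizedWithin = nw, normalizedBetween = nb,
      kwP = kw$p.value, degenerate = FALSE)
}

#' Auditory alignment event for a task variant
#'
#' The event at which the (first or only) auditory stimulus arrives: the first
#' cue in AV trials, the second cue in VA trials, the combined cue in A+V
#' trials, and the stimulus onset in passive-listening trials.
#'
#' @param task task label.
#' @return event column name.
#' @export
auditoryAlignEvent <- function(task) {
  switch(task,
         "AV" = "cue1_onset", "VA" = "cue2_onset", "A+V" = "cue_onset",
         "passive" = "stimulus_onset",
         stop("unknown task: ", task))
}

#' Extract epochs aligned to each trial's auditory event
#'
#' Like [extractEpoch()] but the alignment event is chosen per trial by
#' [auditoryAlignEvent()], so datasets mixing task variants can be aligned to
#' the auditory stimulus throughout.
#'
#' @inheritParams extractEpoch
#' @return a \linkS4class{SpikeEpochs} with \code{alignEvent = "auditory"}.
#' @export
extractAuditoryEpoch <- function(ds, t0, t1) {
  stopifnot(t0 < t1)
  tr <- ds@trials
  trains <- lapply(seq_len(nrow(tr)), function(i) {
    ev <- auditoryAlignEvent(tr$task[i])
    a <- tr[[ev]][i]
    if (is.na(a)) stop("auditory event undefined for trial ", tr$trial_id[i])
    lapply(ds@spikes[[tr$trial_id[i]]], function(s) {
      rel <- s - a
      rel[rel >= t0 & rel < t1]
    })
  })
  names(trains) <- tr$trial_id
  new("SpikeEpochs", trains = trains, trials = tr$trial_id, units = ds@units,
      alignEvent = "auditory", window = c(t0, t1))
}

.concatEpochs <- function(epochList, prefixes) {
  trains <- list(); trials <- character()
  units <- epochList[[1]]@units
  for (k in seq_along(epochList)) {
    ep <- epochList[[k]]
    if (!identical(ep@units, units)) stop("unit sets differ across epochs")
    ids <- paste0(prefixes[k], ":", ep@trials)
    tt <- ep@trains
    names(tt) <- ids
    trains <- c(trains, tt)
    trials <- c(trials, ids)
  }
  new("SpikeEpochs", trains = trains, trials = trials, units = units,
      alignEvent = "mixed", window = epochList[[1]]@window)
}

#' Context-dependent encoding contrast between task and passive listening
#'
#' Embeds, in a single joint SSIMS map, the stimulus-evoked epochs of the
#' multi-modal task trials, the stimulus-evoked epochs of the
#' passive-listening trials, and the pre-stimulus baseline epochs of both,
#' then quantifies (i) the separation between evoked responses across the two
#' listening contexts and (ii) the separation between evoked and baseline
#' activity within each context, all as normalized within/between-category
#' distance statistics.
#'
#' @param dsTask EnsembleDataset of multi-modal task trials (any mix of AV /
#'   VA / A+V; alignment is to each trial's auditory event).
#' @param dsPassive EnsembleDataset of passive-listening trials from the same
#'   units.
#' @param offset start of the evoked window after the auditory event, seconds
#'   (default from [areaOffset()] for the task dataset's area).
#' @param width epoch width, seconds (default 0.5; the baseline epoch is the
#'   \code{width}-long window ending at the event).
#' @param q Victor-Purpura temporal precision (1/s).
#' @param seed embedding seed.
#' @param ... further arguments to [ssimsEmbed()].
#' @return list with elements \code{context} (evoked task vs evoked passive),
#'   \code{taskVsBaseline}, \code{passiveVsBaseline} (each a
#'   \linkS4class{CategoryDistanceStats}), and \code{map} (the joint
#'   \linkS4class{SSIMSMap}).
#' @export
contextContrast <- function(dsTask, dsPassive,
                            offset = areaOffset(area(dsTask)), width = 0.5,
                            q = defaultVPParams()$q, seed = 1, ...) {
  if (!setequal(dsTask@units, dsPassive@units))
    stop("task and passive datasets must share the unit set")
  evTask <- extractAuditoryEpoch(dsTask, offset, offset + width)
  evPass <- extractAuditoryEpoch(dsPassive, offset, offset + width)
  blTask <- extractAuditoryEpoch(dsTask, -width, 0)
  blPass <- extractAuditoryEpoch(dsPassive, -width, 0)
  joint <- .concatEpochs(list(evTask, evPass, blTask, blPass),
                         c("task", "passive", "taskbl", "passbl"))
  feats <- pairwiseFeatures(joint, q = q)
  map <- ssimsEmbed(feats, seed = seed, ...)
  grp <- sub(":.*$", "", map@trials)
  pick <- function(groups, labels) {
    sel <- grp %in% groups
    categoryDistanceStats(map@coordinates[sel, , drop = FALSE], labels[sel])
  }
  context <- setNames(grp, NULL)
  list(
    context = pick(c("task", "passive"), grp),
    taskVsBaseline = pick(c("task", "taskbl"),
                          ifelse(grp == "task", "evoked", "baseline")),
    passiveVsBaseline = pick(c("passive", "passbl"),
                             ifelse(grp == "passive", "evoked", "baseline")),
    map = map)
}
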