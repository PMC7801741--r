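#' Victor-Purpura spike-train edit distance
#'
#' Minimal total cost of transforming one spike train into another using three
#' operations: inserting a spike (cost 1), deleting a spike (cost 1), and
#' moving a spike in time (cost \eqn{q \Delta t}, with \eqn{\Delta t} the size
#' of the shift and \eqn{q} the temporal-precision parameter in 1/s).  At
#' \eqn{q = 0} the metric degenerates to the absolute spike-count difference;
#' large \eqn{q} makes it sensitive to fine spike timing.
#'
#' Computed by dynamic programming over spike indices:
#' \code{D[i,j] = min(D[i-1,j] + 1, D[i,j-1] + 1, D[i-1,j-1] + q|a_i - b_j|)}
#' with \code{D[i,0] = i}, \code{D[0,j] = j}.
#'
#' @param a,b numeric vectors of spike times in seconds, sorted ascending
#'   (possibly empty).
#' @param q temporal precision, 1/seconds, >= 0.  See [calibrateQ()].
#' @return non-negative distance.  Satisfies the metric axioms and the bounds
#'   \code{abs(length(a) - length(b)) <= d <= length(a) + length(b)}.
#' @examples
#' vpDistance(numeric(0), 0.25)          # 1: one deletion
#' vpDistance(0.10, 0.15, q = 20)        # 1: shift 50 ms at q = 20/s
#' vpDistance(0.00, 0.25, q = 20)        # 2: delete + insert beats a 250 ms shift
#' @export
vpDistance <- function(a, b, q = defaultVPParams()$q) {
  stopifnot(q >= 0, all(is.finite(a)), all(is.finite(b)))
  .vp_distance_cpp(as.numeric(a), as.numeric(b), q)
}

#' Calibrate the temporal precision q from an equivalence shift
#'
#' Sets \eqn{q} so that shifting a spike by more than \code{equivalenceShift}
#' costs more than deleting the spike and inserting another: the shift cost
#' \eqn{q \Delta} equals the delete-plus-insert cost 2 exactly at
#' \eqn{\Delta =} \code{equivalenceShift}, hence \eqn{q = 2 /}
#' \code{equivalenceShift}.  The package default uses a 100 ms equivalence
#' shift, i.e. \eqn{q = 20} /s.
#'
#' @param equivalenceShift seconds, > 0.
#' @return list with elements \code{q} (1/s) and \code{equivalenceShift} (s).
#' @examples
#' calibrateQ(0.100)$q  # 20
#' calibrateQ(0.200)$q  # 10
#' @export
calibrateQ <- function(equivalenceShift) {
  if (!is.numeric(equivalenceShift) || length(equivalenceShift) != 1L ||
      !is.finite(equivalenceShift) || equivalenceShift <= 0)
    stop("equivalenceShift must be a single positive number of seconds")
  list(q = 2 / equivalenceShift, equivalenceShift = equivalenceShift)
}

#' @rdname calibrateQ
#' @export
defaultVPParams <- function() calibrateQ(0.100)

#' Brute-force Victor-Purpura distance (reference oracle)
#'
#' Exhaustive minimum over all monotone partial matchings of the spikes of
#' \code{a} to the spikes of \code{b}: for every k, every ordered k-subset of
#' each train is matched in order, with cost \code{q * sum(|dt|)} for the
#' matched spikes plus 1 per unmatched spike.  Independent of the dynamic
#' programme in [vpDistance()] and equal to it on every instance; intended for
#' testing, so the total spike count is capped.
#'
#' @inheritParams vpDistance
#' @param maxSpikes cap on \code{length(a) + length(b)} (default 10).
#' @return the minimal matching cost.
#' @export
vpDistanceBruteForce <- function(a, b, q = defaultVPParams()$q, maxSpikes = 10) {
  na <- length(a); nb <- length(b)
  if (na + nb > maxSpikes)
    stop("brute-force oracle capped at ", maxSpikes, " total spikes")
  best <- na + nb                      # empty matching: delete all, insert all
  for (k in seq_len(min(na, nb))) {
    ia <- if (k == na) matrix(seq_len(na), ncol = 1) else combn(na, k)
    ib <- if (k == nb) matrix(seq_len(nb), ncol = 1) else combn(nb, k)
    for (ca in seq_len(ncol(ia))) for (cb in seq_len(ncol(ib))) {
      ## subsets are in increasing index order -> matching is monotone
      cost <- q * sum(abs(a[ia[, ca]] - b[ib[, cb]])) + (na - k) + (nb - k)
      if (cost < best) best <- cost
    }
  }
  best
}

#' Per-unit pairwise distance matrices over an epoch
#'
#' For every unit, computes the full symmetric trials x trials matrix of
#' Victor-Purpura distances between that unit's spike trains in the given
#' epoch, and horizontally concatenates each trial's distance rows across
#' units into a trials x (trials * units) feature matrix -- the input
#' representation for the SSIMS embedding.
#'
#' @param ds an \linkS4class{EnsembleDataset}, or a
#'   \linkS4class{SpikeEpochs} object already extracted (then
#'   \code{alignEvent}, \code{t0}, \code{t1} are ignored).
#' @param alignEvent,t0,t1 epoch specification passed to [extractEpoch()].
#'   The analyses here default to a 500 ms window starting 200 ms (MFG) or
#'   400 ms (PCG) after cue onset; see [areaOffset()].
#' @param q temporal precision (1/s).
#' @return a \linkS4class{DistanceFeatureSet}.
#' @export
pairwiseFeatures <- function(ds, alignEvent = NULL, t0 = NULL, t1 = NULL,
                             q = defaultVPParams()$q) {
  ep <- if (is(ds, "SpikeEpochs")) ds else extractEpoch(ds, alignEvent, t0, t1)
  n <- length(ep@trials)
  if (n < 2) stop("need at least 2 trials for pairwise distances")
  mats <- lapply(setNames(ep@units, ep@units), function(u) {
    trains <- lapply(ep@trains, function(tt) tt[[u]])
    m <- .vp_pairwise_cpp(unname(trains), q)
    dimnames(m) <- list(ep@trials, ep@trials)
    m
  })
  feats <- do.call(cbind, mats)
  rownames(feats) <- ep@trials
  new("DistanceFeatureSet", unitMatrices = mats, features = feats,
      trials = ep@trials, units = ep@units, q = q)
}

#' Area-specific post-cue analysis offset
#'
#' Evoked-response windows start 200 ms after cue onset for MFG-profile
#' ensembles and 400 ms for PCG-profile ensembles, matching the areas'
#' typical response-onset latencies so that fixed 500 ms windows are centred
#' on the response peaks.
#'
#' @param area "MFG", "PCG" or "other" (treated as MFG-like).
#' @return offset in seconds.
#' @export
areaOffset <- function(area) if (identical(area, "PCG")) 0.4 else 0.2
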