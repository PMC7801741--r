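## Sliding-window multiclass linear decoding with stratified cross-validation
## and label-permutation chance bands.

#' Mean-rate feature matrix for one window
#'
#' @param ds an EnsembleDataset.
#' @param alignEvent event column the window is relative to.
#' @param start window start, seconds relative to the event.
#' @param width window width, seconds.
#' @return trials x units matrix of mean firing rates (spikes/s).
#' @export
windowFeatures <- function(ds, alignEvent, start, width) {
  tr <- ds@trials
  at <- tr[[alignEvent]]
  X <- vapply(ds@units, function(u)
    vapply(seq_len(nrow(tr)), function(i)
      countInWindow(ds@spikes[[tr$trial_id[i]]][[u]], at[i] + start, width),
      numeric(1)) / width,
    numeric(nrow(tr)))
  X <- matrix(X, nrow = nrow(tr),
              dimnames = list(tr$trial_id, ds@units))
  X
}

.stratifiedFolds <- function(y, folds) {
  fid <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    fid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fid
}

## k-fold CV accuracy of a linear maximum-margin classifier; feature
## standardization is fit on the training folds only (no leakage).
.cvAccuracy <- function(X, y, foldId, folds, cost = 1) {
  correct <- 0L
  for (f in seq_len(folds)) {
    tr <- foldId != f
    ytr <- droplevels(y[tr])
    mu <- colMeans(X[tr, , drop = FALSE])
    s <- apply(X[tr, , drop = FALSE], 2, sd)
    s[!is.finite(s) | s == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, s, "/")
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, s, "/")
    m <- e1071::svm(Xtr, ytr, kernel = "linear", cost = cost, scale = FALSE)
    correct <- correct + sum(as.character(predict(m, Xte)) ==
                               as.character(y[!tr]))
  }
  correct / length(y)
}

#' Sliding-window population decoding with permutation chance bands
#'
#' For each window of the grid, decodes the trial label from the ensemble's
#' mean-rate feature vector with a linear maximum-margin classifier (libsvm;
#' multiclass handled by exhaustive one-vs-one coding) under stratified
#' k-fold cross-validation.  Feature standardization is fit on training folds
#' only.  The fold assignment is drawn once from \code{seed} and reused across
#' windows so the accuracy time course is comparable window to window.
#'
#' When \code{nPerm > 0}, a chance band is estimated by re-running the full
#' cross-validation on label-shuffled data: each permutation shuffles the
#' labels once and reuses that shuffle across all windows (preserving the
#' temporal coherence of the null), and the band is the per-window empirical
#' quantile range of the permuted accuracies.
#'
#' @param ds an EnsembleDataset.
#' @param alignEvent event column the window grid is relative to.
#' @param grid a [windowGrid()] (the analyses here default to 300 ms windows
#'   stepped across the transition of interest).
#' @param labelKey trial column to decode.
#' @param folds number of cross-validation folds (default 5).
#' @param nPerm number of label permutations for the chance band (0 = none;
#'   10000 at full scale, >= 200 in scaled-down desk runs).
#' @param quantiles band quantiles (default 2.5\% and 97.5\%).
#' @param cost margin penalty of the classifier (default 1).
#' @param seed integer seed for folds and permutations.
#' @return a \linkS4class{DecodingResult}.
#' @export
slidingDecode <- function(ds, alignEvent, grid, labelKey, folds = 5,
                          nPerm = 0, quantiles = c(0.025, 0.975), cost = 1,
                          seed = 1) {
  y <- factor(as.character(ds@trials[[labelKey]]))
  if (anyNA(ds@trials[[labelKey]])) stop("missing labels in '", labelKey, "'")
  tab <- table(y)
  if (any(tab < folds))
    stop("class(es) with fewer trials than folds: ",
         paste(names(tab)[tab < folds], collapse = ", "))
  win <- makeWindows(grid)
  .withSeed(seed, {
    foldId <- .stratifiedFolds(y, folds)
    perms <- if (nPerm > 0) replicate(nPerm, sample(seq_along(y))) else NULL
    acc <- numeric(nrow(win))
    bandLow <- bandHigh <- rep(NA_real_, nrow(win))
    for (k in seq_len(nrow(win))) {
      X <- windowFeatures(ds, alignEvent, win$start[k], grid$width)
      acc[k] <- .cvAccuracy(X, y, foldId, folds, cost)
      if (nPerm > 0) {
        pa <- vapply(seq_len(nPerm), function(j)
          .cvAccuracy(X, y[perms[, j]], foldId, folds, cost), numeric(1))
        qs <- quantile(pa, quantiles, names = FALSE)
        bandLow[k] <- qs[1]
        bandHigh[k] <- qs[2]
      }
    }
    tabout <- data.frame(window_start = win$start, accuracy = acc)
    if (nPerm > 0) {
      tabout$band_low <- bandLow
      tabout$band_high <- bandHigh
    }
    new("DecodingResult", table = tabout, labelKey = labelKey,
        nClasses = length(tab), folds = as.integer(folds),
        nPerm = as.integer(nPerm), seed = as.integer(seed))
  })
}

#' @rdname slidingDecode
#' @param nPerm number of permutations (>= 100).
#' @return \code{permutationBand}: data.frame with \code{window_start},
#'   \code{band_low}, \code{band_high}.
#' @export
permutationBand <- function(ds, alignEvent, grid, labelKey, nPerm = 200,
                            quantiles = c(0.025, 0.975), folds = 5, cost = 1,
                            seed = 1) {
  if (nPerm < 100) stop("nPerm must be at least 100")
  res <- slidingDecode(ds, alignEvent, grid, labelKey, folds = folds,
                       nPerm = nPerm, quantiles = quantiles, cost = cost,
                       seed = seed)
  res@table[, c("window_start", "band_low", "band_high")]
}

#' @rdname slidingDecode
#' @param object a DecodingResult.
#' @export
setGeneric("decodingTable", function(object) standardGeneric("decodingTable"))
#' @rdname slidingDecode
#' @export
setMethod("decodingTable", "DecodingResult", function(object) object@table)
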