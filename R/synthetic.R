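## Synthetic ensembles: inhomogeneous-Poisson units with event-locked,
## condition-gated multiplicative gain components, emulating the multi-modal
## cued-movement and passive-listening paradigms with known ground truth.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Response components and tuning profiles (simulation ground truth)
#'
#' A response component multiplies a unit's baseline rate by a
#' condition-dependent gain in a window locked to a trial event.  Gains are
#' multiplicative (gain 1 = no change); unequal gains across condition labels
#' make the unit selective for that condition.  The \code{"boxcar"} shape
#' applies the gain uniformly over \code{[trigger + onset, trigger + onset +
#' duration)}; the \code{"alpha"} shape scales the gain's excess by
#' \code{(s/ta) * exp(1 - s/ta)} with \code{s} the time since onset and
#' \code{ta = duration / 4}, giving a rounded transient that peaks at
#' \code{ta}.
#'
#' @param trigger event column name the component is locked to.
#' @param gains named numeric vector of gains keyed by condition label, or a
#'   single unnamed gain applied regardless of condition.  Labels absent from
#'   the vector get gain 1.
#' @param onset latency from the trigger event to response onset, seconds >= 0.
#' @param duration response duration, seconds > 0.
#' @param conditionKey trial column supplying the condition label
#'   (\code{"auditory_cue"}, \code{"visual_cue"}, \code{"target_id"}, ...);
#'   ignored for unnamed gains.
#' @param shape \code{"boxcar"} or \code{"alpha"}.
#' @param tasks task variants in which the component is active (NULL = all).
#' @return \code{responseComponent}: a list describing one component;
#'   \code{tuningProfile}: a list with the unit id, baseline rate (spikes/s)
#'   and component list.
#' @export
responseComponent <- function(trigger, gains, onset, duration,
                              conditionKey = NULL,
                              shape = c("boxcar", "alpha"), tasks = NULL) {
  shape <- match.arg(shape)
  stopifnot(onset >= 0, duration > 0, all(gains >= 0))
  if (!is.null(names(gains)) && is.null(conditionKey))
    stop("named gains require a conditionKey")
  list(trigger = trigger, conditionKey = conditionKey, gains = gains,
       onset = onset, duration = duration, shape = shape, tasks = tasks)
}

#' @rdname responseComponent
#' @param unitId unit identifier.
#' @param baselineRate baseline firing rate, spikes/s, >= 0.
#' @param components list of response components.
#' @export
tuningProfile <- function(unitId, baselineRate, components = list()) {
  stopifnot(baselineRate >= 0)
  list(unitId = unitId, baselineRate = baselineRate, components = components)
}

.componentGain <- function(comp, trial) {
  if (is.null(names(comp$gains))) return(unname(comp$gains[1]))
  lab <- trial[[comp$conditionKey]]
  if (is.null(lab) || is.na(lab)) return(1)
  g <- comp$gains[as.character(lab)]
  if (is.na(g)) 1 else unname(g)
}

.componentActive <- function(comp, trial) {
  (is.null(comp$tasks) || trial$task %in% comp$tasks) &&
    !is.null(trial[[comp$trigger]]) && !is.na(trial[[comp$trigger]])
}

#' Instantaneous firing rate of a simulated unit
#'
#' Evaluates the generative intensity: baseline rate times the product of all
#' active components' gains at time \code{t}.
#'
#' @param profile a [tuningProfile()].
#' @param trial one trial record as a list (a row of the trial table),
#'   supplying event times (session clock) and condition labels.
#' @param t numeric vector of session-clock times.
#' @return spikes/s at each \code{t}.
#' @export
rateFunction <- function(profile, trial, t) {
  rate <- rep(profile$baselineRate, length(t))
  for (comp in profile$components) {
    if (!.componentActive(comp, trial)) next
    g <- .componentGain(comp, trial)
    s <- t - (trial[[comp$trigger]] + comp$onset)
    inwin <- s >= 0 & s < comp$duration
    if (!any(inwin)) next
    mult <- rep(1, length(t))
    if (comp$shape == "boxcar") {
      mult[inwin] <- g
    } else {
      ta <- comp$duration / 4
      mult[inwin] <- 1 + (g - 1) * (s[inwin] / ta) * exp(1 - s[inwin] / ta)
    }
    rate <- rate * mult
  }
  rate
}

## exact upper bound of rateFunction over a trial (per-component peak gains)
.rateBound <- function(profile, trial) {
  b <- profile$baselineRate
  for (comp in profile$components)
    if (.componentActive(comp, trial))
      b <- b * max(1, .componentGain(comp, trial))
  b
}

#' Scenario configuration for ensemble simulation
#'
#' Trial counts, timing and cue vocabulary of the simulated paradigms.
#' Sequential trials (AV, VA) insert a variable 1-2 s delay before each cue
#' and before the go signal; simultaneous (A+V) trials have a single combined
#' cue; passive trials present one of six auditory stimuli with no behavioural
#' requirement.  Each target identity is the unique combination of an auditory
#' colour cue and a visual shape cue.  Condition labels are balanced within
#' each task variant (counts differ by at most 1).
#'
#' @param area recording-site tag for the generated dataset.
#' @param nUnits number of units.
#' @param nTrials named integer vector of trials per task variant; variants
#'   with 0 trials are omitted.
#' @param delayRange min/max of each variable delay, seconds.
#' @param auditoryCues,visualCues instructional cue vocabularies (2 each).
#' @param passiveStimuli labels of the passive-listening stimuli (6).
#' @param profiles list of [tuningProfile()]s, one per unit.
#' @param seed integer seed governing design and spikes.
#' @return a list with class \code{"scenarioConfig"}.
#' @export
scenarioConfig <- function(area = "other", nUnits = 40,
                           nTrials = c(AV = 72, VA = 72, "A+V" = 72, passive = 144),
                           delayRange = c(1, 2),
                           auditoryCues = c("red", "blue"),
                           visualCues = c("circle", "square"),
                           passiveStimuli = c("red", "pink", "north", "south",
                                              "tone523", "tone1047"),
                           profiles = NULL, seed = 1) {
  stopifnot(all(delayRange > 0), diff(delayRange) >= 0)
  structure(list(area = area, nUnits = nUnits, nTrials = nTrials,
                 delayRange = delayRange, auditoryCues = auditoryCues,
                 visualCues = visualCues, passiveStimuli = passiveStimuli,
                 profiles = profiles, seed = seed),
            class = "scenarioConfig")
}

.balancedLabels <- function(labels, n) sample(rep_len(labels, n))

.simulateTrialTable <- function(config) {
  cfg <- config
  dmin <- cfg$delayRange[1]; dmax <- cfg$delayRange[2]
  targets <- as.vector(outer(cfg$auditoryCues, cfg$visualCues, paste, sep = "_"))
  rows <- list()
  clock <- 0
  for (task in names(cfg$nTrials)) {
    n <- cfg$nTrials[[task]]
    if (n < 1) next
    if (task == "passive") {
      stim <- .balancedLabels(cfg$passiveStimuli, n)
    } else {
      tg <- .balancedLabels(targets, n)
      aud <- sub("_.*$", "", tg)
      vis <- sub("^.*_", "", tg)
    }
    for (i in seq_len(n)) {
      start <- clock
      if (task %in% c("AV", "VA")) {
        cue1 <- start + runif(1, dmin, dmax)
        cue2 <- cue1 + runif(1, dmin, dmax)
        go <- cue2 + runif(1, dmin, dmax)
        end <- go + 1.5
        row <- data.frame(trial_id = sprintf("%s_%03d", task, i),
                          session_id = "sim", task = task,
                          auditory_cue = aud[i], visual_cue = vis[i],
                          target_id = tg[i], outcome = "success",
                          trial_start = start, cue1_onset = cue1,
                          cue2_onset = cue2, go_onset = go, trial_end = end,
                          cue_onset = NA_real_, stimulus_onset = NA_real_)
      } else if (task == "A+V") {
        cue <- start + runif(1, dmin, dmax)
        go <- cue + runif(1, dmin, dmax)
        end <- go + 1.5
        row <- data.frame(trial_id = sprintf("AplusV_%03d", i),
                          session_id = "sim", task = task,
                          auditory_cue = aud[i], visual_cue = vis[i],
                          target_id = tg[i], outcome = "success",
                          trial_start = start, cue1_onset = NA_real_,
                          cue2_onset = NA_real_, go_onset = go,
                          trial_end = end, cue_onset = cue,
                          stimulus_onset = NA_real_)
      } else {
        son <- start + runif(1, dmin, dmax)
        end <- son + 1.5
        row <- data.frame(trial_id = sprintf("passive_%03d", i),
                          session_id = "sim", task = task,
                          auditory_cue = stim[i], visual_cue = NA_character_,
                          target_id = NA_character_, outcome = "success",
                          trial_start = start, cue1_onset = NA_real_,
                          cue2_onset = NA_real_, go_onset = NA_real_,
                          trial_end = end, cue_onset = NA_real_,
                          stimulus_onset = son)
      }
      rows[[length(rows) + 1L]] <- row
      clock <- row$trial_end + 1
    }
  }
  do.call(rbind, rows)
}

## inhomogeneous Poisson draw over [t0, t1) by thinning against `bound`
.thinPoisson <- function(profile, trial, t0, t1, bound) {
  if (bound <= 0) return(numeric(0))
  n <- rpois(1, bound * (t1 - t0))
  if (n == 0) return(numeric(0))
  cand <- sort(runif(n, t0, t1))
  keep <- runif(n) < rateFunction(profile, trial, cand) / bound
  cand[keep]
}

#' Simulate an ensemble dataset from tuning profiles
#'
#' Draws the trial design (variable delays, balanced condition labels) and
#' then spikes for every unit and trial from an inhomogeneous Poisson process
#' whose intensity is [rateFunction()], via thinning against the exact
#' per-trial maximum rate.  Deterministic given \code{config$seed}.
#'
#' @param config a [scenarioConfig()] with non-NULL \code{profiles}.
#' @return list with elements \code{dataset} (an
#'   \linkS4class{EnsembleDataset}), \code{profiles} (the ground-truth
#'   tuning profiles) and \code{groundTruth} (the same as a flat data.frame:
#'   unit_id, component, trigger, condition, gain, onset_latency, duration,
#'   shape).
#' @export
simulateEnsemble <- function(config) {
  stopifnot(inherits(config, "scenarioConfig"))
  if (is.null(config$profiles))
    stop("config$profiles must supply one tuningProfile per unit")
  if (length(config$profiles) != config$nUnits)
    stop("need exactly nUnits profiles")
  .withSeed(config$seed, {
    trials <- .simulateTrialTable(config)
    unit_ids <- vapply(config$profiles, `[[`, "", "unitId")
    spikes <- lapply(seq_len(nrow(trials)), function(i) {
      trial <- as.list(trials[i, , drop = FALSE])
      st <- lapply(config$profiles, function(p)
        .thinPoisson(p, trial, trial$trial_start, trial$trial_end,
                     .rateBound(p, trial)))
      names(st) <- unit_ids
      st
    })
    names(spikes) <- trials$trial_id
    ds <- new("EnsembleDataset", area = config$area, units = unit_ids,
              trials = trials, spikes = spikes)
    list(dataset = ds, profiles = config$profiles,
         groundTruth = groundTruthTable(config$profiles))
  })
}

#' @rdname simulateEnsemble
#' @param profiles list of tuning profiles.
#' @export
groundTruthTable <- function(profiles) {
  rows <- list()
  for (p in profiles) for (ci in seq_along(p$components)) {
    comp <- p$components[[ci]]
    gains <- comp$gains
    cond <- if (is.null(names(gains))) "*" else names(gains)
    rows[[length(rows) + 1L]] <- data.frame(
      unit_id = p$unitId, component = ci, trigger = comp$trigger,
      condition = cond, gain = as.numeric(gains),
      onset_latency = comp$onset, duration = comp$duration,
      shape = comp$shape)
  }
  if (!length(rows))
    return(data.frame(unit_id = character(0), component = integer(0),
                      trigger = character(0), condition = character(0),
                      gain = numeric(0), onset_latency = numeric(0),
                      duration = numeric(0), shape = character(0)))
  do.call(rbind, rows)
}

#' Two-area reference scenario
#'
#' Builds matched MFG-like and PCG-like ensembles covering the AV, VA, A+V
#' and passive-listening task variants, with the response phenomenology the
#' analyses in this package are designed to detect:
#' \itemize{
#'   \item MFG-like units: a fraction (default 0.5) respond to auditory cue
#'     onsets with short latencies (uniform 150-210 ms, median 180 ms);
#'     half of those are cue-selective (unequal gains for the two auditory
#'     cues); a 24\% subset also responds non-selectively (equal gains) to the
#'     passive stimuli at a weaker gain, so task context modulates their
#'     evoked response; no unit responds to visual cue onsets; about a third
#'     are non-selectively active after the go cue.
#'   \item PCG-like units: a fraction (default 0.7) respond with
#'     target-dependent gains only after the final informative cue (the second
#'     cue in AV/VA, the combined cue in A+V) with longer latencies (uniform
#'     390-450 ms, median 420 ms) and remain target-selective through the go
#'     phase; none respond to passive stimuli.
#' }
#' The 240 ms separation between the area's median onset latencies is the
#' injected ground truth for latency-recovery tests.
#'
#' @param seed integer seed; the two areas use \code{seed} and \code{seed + 1}.
#' @param nUnits units per area.
#' @param nTrials trials per active task variant (AV, VA, A+V).
#' @param nPassive passive-listening trials.
#' @param fracAuditoryMFG fraction of MFG-like units responding to auditory
#'   cues in the task.
#' @param fracPassiveMFG fraction of MFG-like units responding to passive
#'   stimuli.
#' @param fracTargetPCG fraction of PCG-like units with target-tuned
#'   responses.
#' @return list with elements \code{MFG} and \code{PCG}, each as returned by
#'   [simulateEnsemble()].
#' @export
multimodalScenario <- function(seed = 1, nUnits = 40, nTrials = 72,
                               nPassive = 144, fracAuditoryMFG = 0.5,
                               fracPassiveMFG = 0.24, fracTargetPCG = 0.7) {
  nT <- c(AV = nTrials, VA = nTrials, "A+V" = nTrials, passive = nPassive)
  mfg <- .withSeed(seed * 1000L + 17L,
                   .mfgProfiles(nUnits, fracAuditoryMFG, fracPassiveMFG))
  pcg <- .withSeed(seed * 1000L + 29L, .pcgProfiles(nUnits, fracTargetPCG))
  list(
    MFG = simulateEnsemble(scenarioConfig(area = "MFG", nUnits = nUnits,
                                          nTrials = nT, profiles = mfg,
                                          seed = seed)),
    PCG = simulateEnsemble(scenarioConfig(area = "PCG", nUnits = nUnits,
                                          nTrials = nT, profiles = pcg,
                                          seed = seed + 1L)))
}

## MFG-like profiles: aurally responsive, early, selective only for
## action-relevant auditory cues, non-selective to passive sounds, untuned
## go-phase activity in a third of units.
.mfgProfiles <- function(nUnits, fracAuditory, fracPassive) {
  nAud <- round(fracAuditory * nUnits)
  nSel <- floor(nAud / 2)
  nPas <- round(fracPassive * nUnits)
  nGo <- floor(nUnits / 3)
  lapply(seq_len(nUnits), function(i) {
    comps <- list()
    if (i <= nAud) {
      lat <- runif(1, 0.15, 0.21)
      gains <- if (i <= nSel) {
        if (i %% 2) c(red = 3.5, blue = 1.5) else c(red = 1.5, blue = 3.5)
      } else c(red = 3, blue = 3)
      comps <- c(comps, list(
        responseComponent("cue1_onset", gains, lat, 0.8,
                          conditionKey = "auditory_cue", tasks = "AV"),
        responseComponent("cue2_onset", gains, lat, 0.8,
                          conditionKey = "auditory_cue", tasks = "VA"),
        responseComponent("cue_onset", gains, lat, 0.8,
                          conditionKey = "auditory_cue", tasks = "A+V")))
      if (i <= nPas)
        comps <- c(comps, list(
          responseComponent("stimulus_onset", 1.8, lat, 0.8,
                            tasks = "passive")))
    }
    if (i <= nGo)
      comps <- c(comps, list(
        responseComponent("go_onset", 2.5, 0.15, 1.0,
                          tasks = c("AV", "VA", "A+V"))))
    tuningProfile(sprintf("mfg%02d", i), runif(1, 5, 15), comps)
  })
}

## PCG-like profiles: target-tuned only once the target is fully specified,
## later onset, strongly engaged and still selective in the go phase, silent
## to passive sounds.
.pcgProfiles <- function(nUnits, fracTarget) {
  nTgt <- round(fracTarget * nUnits)
  targets <- c("red_circle", "red_square", "blue_circle", "blue_square")
  lapply(seq_len(nUnits), function(i) {
    comps <- list()
    if (i <= nTgt) {
      lat <- runif(1, 0.39, 0.45)
      pref <- targets[(i - 1) %% 4 + 1]
      gains <- setNames(rep(1.3, 4), targets)
      gains[pref] <- 4
      comps <- list(
        responseComponent("cue2_onset", gains, lat, 0.8,
                          conditionKey = "target_id", tasks = c("AV", "VA")),
        responseComponent("cue_onset", gains, lat, 0.8,
                          conditionKey = "target_id", tasks = "A+V"),
        responseComponent("go_onset", gains, 0.2, 1.2,
                          conditionKey = "target_id",
                          tasks = c("AV", "VA", "A+V")))
    }
    tuningProfile(sprintf("pcg%02d", i), runif(1, 5, 15), comps)
  })
}
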