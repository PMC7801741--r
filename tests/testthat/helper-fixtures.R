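## fixtures are built in code: tiny hand-placed datasets plus parameterized
## simulated ensembles

## two-unit, three-trial AV dataset with hand-placed spikes
tinyDataset <- function() {
  trials <- data.frame(
    trial_id = c("t1", "t2", "t3"), session_id = "s1", task = "AV",
    auditory_cue = c("red", "blue", "red"),
    visual_cue = c("circle", "circle", "square"),
    target_id = c("red_circle", "blue_circle", "red_square"),
    outcome = c("success", "success", "false_start"),
    trial_start = c(0, 10, 20), cue1_onset = c(1.5, 11.5, 21.5),
    cue2_onset = c(3, 13, 23), go_onset = c(4.5, 14.5, 24.5),
    trial_end = c(6, 16, 26))
  spikes <- data.frame(
    trial_id = c("t1", "t1", "t1", "t2", "t3"),
    unit_id = c("u1", "u1", "u2", "u1", "u2"),
    spike_time = c(1.60, 1.80, 2.25, 11.55, 21.90))
  ensembleDataset("MFG", trials, spikes, units = c("u1", "u2"))
}

## ensemble of constant-rate (null) Poisson units on one task variant
nullEnsemble <- function(nUnits, nTrials, task = "AV", seed = 1,
                         rateRange = c(5, 15), nPassiveStimuli = 6) {
  profiles <- lapply(seq_len(nUnits), function(i)
    tuningProfile(sprintf("u%03d", i),
                  rateRange[1] + (i - 1) %% 7 / 6 * diff(rateRange)))
  nT <- setNames(nTrials, task)
  simulateEnsemble(scenarioConfig(nUnits = nUnits, nTrials = nT,
                                  profiles = profiles, seed = seed))$dataset
}

## ensemble of boxcar-response units locked to the first AV cue
boxcarEnsemble <- function(nUnits, nTrials, gain = 5, onset = 0.3,
                           duration = 0.5, seed = 1, conditionKey = NULL,
                           gains = NULL, baseline = 10) {
  profiles <- lapply(seq_len(nUnits), function(i) {
    g <- if (is.null(gains)) gain else gains
    tuningProfile(sprintf("u%03d", i), baseline, list(
      responseComponent("cue1_onset", g, onset, duration,
                        conditionKey = conditionKey, tasks = "AV")))
  })
  simulateEnsemble(scenarioConfig(nUnits = nUnits,
                                  nTrials = c(AV = nTrials),
                                  profiles = profiles, seed = seed))$dataset
}

## random sorted spike train for metric property sweeps
randomTrain <- function(maxSpikes = 8, span = 1) {
  n <- sample(0:maxSpikes, 1)
  sort(runif(n, 0, span))
}

## mean silhouette width of a 2-group labelling on coordinates
meanSilhouette <- function(coords, labels) {
  D <- as.matrix(dist(coords))
  n <- nrow(D)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
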