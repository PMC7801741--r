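test_that("responsiveness flags exactly the driven windows", {
  ## gain 4 from 0.2 to 0.7 s after the first cue, 60 trials
  ds <- boxcarEnsemble(1, 60, gain = 4, onset = 0.2, duration = 0.5, seed = 61)
  g <- windowGrid(-0.3, 0.8, 0.3, 0.1)
  res <- classifyResponsive(ds, "u001", "cue1_onset", g)
  expect_true(all(res$p >= 0 & res$p <= 1))
  ## windows fully inside the response are significant
  inside <- res$window_start >= 0.2 & res$window_start + 0.3 <= 0.7
  expect_true(all(res$significant[inside]))
  ## windows fully before the cue are not
  before <- res$window_start + 0.3 <= 0
  expect_false(any(res$significant[before]))
})

test_that("identical baseline and window samples give p near 1", {
  ds <- nullEnsemble(1, 20, seed = 62)
  ## a window that IS the baseline window: same per-trial counts
  g <- windowGrid(-0.3, 0, 0.3, 0.1)
  res <- classifyResponsive(ds, "u001", "cue1_onset", g)
  expect_gt(res$p[1], 0.9)
  expect_false(res$significant[1])
})

test_that("selectivity tracks condition-dependent gains, not responsiveness", {
  ds <- boxcarEnsemble(1, 60, onset = 0.2, duration = 0.5, seed = 63,
                       conditionKey = "auditory_cue",
                       gains = c(red = 3, blue = 1))
  g <- windowGrid(-0.3, 0.8, 0.3, 0.1)
  sel <- classifySelective(ds, "u001", "cue1_onset", g,
                           groupBy = "auditory_cue")
  inside <- sel$window_start >= 0.2 & sel$window_start + 0.3 <= 0.7
  before <- sel$window_start + 0.3 <= 0
  expect_true(all(sel$significant[inside]))
  expect_false(any(sel$significant[before]))

  ## equal gains across conditions: responsive but not selective
  ds2 <- boxcarEnsemble(1, 60, gain = 3, onset = 0.2, duration = 0.5,
                        seed = 64)
  sel2 <- classifySelective(ds2, "u001", "cue1_onset", g,
                            groupBy = "auditory_cue")
  expect_false(any(sel2$significant[inside][1:2]))

  ## shuffling the labels destroys selectivity in >= 95% of reshuffles
  set.seed(65)
  hits <- replicate(50, {
    dss <- ds
    dss@trials$auditory_cue <- sample(dss@trials$auditory_cue)
    g1 <- windowGrid(0.25, 0.65, 0.3, 0.3)
    classifySelective(dss, "u001", "cue1_onset", g1,
                      groupBy = "auditory_cue")$significant[1]
  })
  expect_gte(mean(!hits), 0.95)

  ## small condition groups are rejected by name
  ds3 <- filterTrials(ds, function(tr) tr$trial_id %in%
                        trialTable(ds)$trial_id[1:7])
  expect_error(classifySelective(ds3, "u001", "cue1_onset", g,
                                 groupBy = "target_id"), "< 3 trials")
})

test_that("power is monotone in gain and trial count", {
  g <- windowGrid(0.25, 0.65, 0.3, 0.3)   # one window inside the response
  rate <- function(gain, n) {
    ds <- boxcarEnsemble(12, n, gain = gain, onset = 0.2, duration = 0.5,
                         seed = 66)
    mean(vapply(unitIds(ds), function(u)
      classifyResponsive(ds, u, "cue1_onset", g)$significant[1], logical(1)))
  }
  p_lo_small <- rate(1.3, 12)
  p_hi_small <- rate(3.0, 12)
  p_hi_large <- rate(3.0, 48)
  expect_lte(p_lo_small, p_hi_small)
  expect_lte(p_hi_small, p_hi_large)
  expect_equal(p_hi_large, 1)
})

test_that("ensemble fractions aggregate unit classifications", {
  ds <- boxcarEnsemble(4, 30, gain = 5, onset = 0.1, duration = 0.6, seed = 67)
  g <- windowGrid(-0.3, 0.7, 0.3, 0.2)
  res <- do.call(rbind, lapply(unitIds(ds), function(u)
    classifyResponsive(ds, u, "cue1_onset", g)))
  fr <- ensembleFractionTimecourse(res)
  expect_equal(unique(fr$n_units), 4)
  ## all units driven hard: fraction 1 in the covered window
  expect_equal(fr$fraction[abs(fr$window_start - 0.3) < 1e-9], 1)
  expect_equal(fr$fraction[abs(fr$window_start + 0.3) < 1e-9], 0)
})

test_that("aural responsiveness applies the Bonferroni correction", {
  ## passive listening, responsive to every stimulus equally
  profiles <- list(tuningProfile("u1", 8, list(
    responseComponent("stimulus_onset", 3, 0.15, 0.6, tasks = "passive"))))
  ds <- simulateEnsemble(scenarioConfig(
    area = "MFG", nUnits = 1, nTrials = c(passive = 48),
    profiles = profiles, seed = 71))$dataset
  fl <- auralResponsiveness(ds, "u1")
  expect_true(fl$responsive)
  expect_equal(fl$correction, 6)
  expect_equal(fl$threshold, 0.01 / 6)
  expect_length(fl$p, 6)
  ## equal gains: responsive but not selective
  expect_false(auralSelectivity(ds, "u1")$selective)
})

test_that("aural selectivity detects unequal stimulus gains", {
  profiles <- list(tuningProfile("u1", 8, list(
    responseComponent("cue1_onset", c(red = 4, blue = 1), 0.15, 0.6,
                      conditionKey = "auditory_cue", tasks = "AV"))))
  ds <- simulateEnsemble(scenarioConfig(
    area = "MFG", nUnits = 1, nTrials = c(AV = 40),
    profiles = profiles, seed = 72))$dataset
  expect_true(auralSelectivity(ds, "u1")$selective)
})

test_that("context modulation compares task cues to pooled passive sounds", {
  profiles <- list(
    tuningProfile("mod", 8, list(
      responseComponent("cue1_onset", 3, 0.15, 0.6, tasks = "AV"),
      responseComponent("stimulus_onset", 1, 0.15, 0.6, tasks = "passive"))),
    tuningProfile("same", 8, list(
      responseComponent("cue1_onset", 2.5, 0.15, 0.6, tasks = "AV"),
      responseComponent("stimulus_onset", 2.5, 0.15, 0.6, tasks = "passive"))))
  sim <- simulateEnsemble(scenarioConfig(
    area = "MFG", nUnits = 2, nTrials = c(AV = 40, passive = 60),
    profiles = profiles, seed = 73))$dataset
  dsT <- filterTrials(sim, function(tr) tr$task == "AV")
  dsP <- filterTrials(sim, function(tr) tr$task == "passive")
  expect_true(contextModulation(dsT, dsP, "mod")$modulated)
  expect_false(contextModulation(dsT, dsP, "same")$modulated)
  expect_error(contextModulation(dsT, dsP, "nope"), "both datasets")
})
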