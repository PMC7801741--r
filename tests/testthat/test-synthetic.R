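test_that("rate function composes multiplicative gain components", {
  trial <- list(task = "AV", auditory_cue = "red", trial_start = 0,
                cue1_onset = 1, cue2_onset = 2.5, go_onset = 4, trial_end = 5)
  ## no components: constant baseline
  p0 <- tuningProfile("u", 10)
  expect_equal(rateFunction(p0, trial, c(0, 1, 4.9)), c(10, 10, 10))
  ## boxcar gain 3 on [trigger+0.2, trigger+0.7)
  p1 <- tuningProfile("u", 10, list(
    responseComponent("cue1_onset", 3, 0.2, 0.5)))
  expect_equal(rateFunction(p1, trial, 1 + c(0.19, 0.2, 0.45, 0.699, 0.7)),
               c(10, 30, 30, 30, 10))
  ## overlapping boxcars multiply
  p2 <- tuningProfile("u", 10, list(
    responseComponent("cue1_onset", 2, 0.2, 0.5),
    responseComponent("cue1_onset", 3, 0.3, 0.2)))
  expect_equal(rateFunction(p2, trial, 1 + c(0.25, 0.35, 0.6)), c(20, 60, 20))
  ## condition gating: a blue-keyed gain is inert on a red trial
  p3 <- tuningProfile("u", 10, list(
    responseComponent("cue1_onset", c(blue = 5), 0.2, 0.5,
                      conditionKey = "auditory_cue")))
  expect_equal(rateFunction(p3, trial, 1.3), 10)
  ## alpha shape peaks at duration/4 with the full gain excess
  p4 <- tuningProfile("u", 10, list(
    responseComponent("cue1_onset", 3, 0, 0.4, shape = "alpha")))
  expect_equal(rateFunction(p4, trial, 1 + 0.1), 30)   # s = ta = 0.1
  expect_lt(rateFunction(p4, trial, 1 + 0.3), 30)
  expect_equal(rateFunction(p4, trial, 0.99), 10)
})

test_that("simulated counts have the Poisson mean and are seed-stable", {
  ds <- nullEnsemble(1, 200, seed = 31, rateRange = c(20, 20))
  counts <- vapply(trialTable(ds)$trial_id, function(t) {
    tr <- trialTable(ds)[trialTable(ds)$trial_id == t, ]
    countInWindow(spikeTrain(ds, t, "u001"), tr$trial_start, 1)
  }, numeric(1))
  ## mean count over 1 s epochs within 3 standard errors of the rate
  se <- sqrt(20 / 200)
  expect_lt(abs(mean(counts) - 20), 3 * se)

  ds2 <- nullEnsemble(1, 200, seed = 31, rateRange = c(20, 20))
  expect_identical(ds@spikes, ds2@spikes)
  expect_identical(trialTable(ds), trialTable(ds2))
})

test_that("time-rescaled inter-spike intervals are unit-rate exponential", {
  ## boxcar intensity has a closed-form cumulative: r0*t + r0*(g-1)*overlap
  profiles <- list(tuningProfile("u1", 12, list(
    responseComponent("cue1_onset", 4, 0.2, 0.5, tasks = "AV"))))
  ds <- simulateEnsemble(scenarioConfig(nUnits = 1, nTrials = c(AV = 250),
                                        profiles = profiles, seed = 7))$dataset
  tr <- trialTable(ds)
  Lambda <- function(t, start, a, b) {
    12 * (t - start) + 12 * 3 * pmin(pmax(t - a, 0), b - a)
  }
  u <- unlist(lapply(seq_len(nrow(tr)), function(i) {
    s <- spikeTrain(ds, tr$trial_id[i], "u1")
    if (length(s) < 2) return(numeric(0))
    a <- tr$cue1_onset[i] + 0.2
    diff(Lambda(s, tr$trial_start[i], a, a + 0.5))
  }))
  expect_gt(length(u), 5000)
  ks <- suppressWarnings(stats::ks.test(u, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("thinning is invariant to inflating the dominating bound", {
  profile <- tuningProfile("u", 8, list(
    responseComponent("cue1_onset", 3, 0.2, 0.5, tasks = "AV")))
  trial <- list(task = "AV", trial_start = 0, cue1_onset = 1, cue2_onset = 2.5,
                go_onset = 4, trial_end = 5)
  draw <- function(bound, seed) {
    set.seed(seed)
    vapply(1:2000, function(i)
      length(planspike:::.thinPoisson(profile, trial, 0, 5, bound)),
      numeric(1))
  }
  exact <- draw(24, 1)       # exact bound: 8 * 3
  inflated <- draw(60, 2)    # any larger bound must give the same law
  expect_gt(suppressWarnings(stats::ks.test(exact, inflated))$p.value, 0.01)
  expect_lt(abs(mean(exact) - mean(inflated)), 3 * sd(exact) / sqrt(1000))
})

test_that("designs are balanced and task events are well-formed", {
  scen <- multimodalScenario(seed = 13, nUnits = 4, nTrials = 30, nPassive = 32)
  for (a in c("MFG", "PCG")) {
    tr <- trialTable(scen[[a]]$dataset)
    for (task in c("AV", "VA", "A+V")) {
      tab <- table(tr$target_id[tr$task == task])
      expect_lte(diff(range(tab)), 1)
    }
    tab <- table(tr$auditory_cue[tr$task == "passive"])
    expect_lte(diff(range(tab)), 1)
    expect_equal(length(tab), 6L)
    ## variable delays within [1, 2] s
    av <- tr[tr$task == "AV", ]
    d <- cbind(av$cue1_onset - av$trial_start, av$cue2_onset - av$cue1_onset,
               av$go_onset - av$cue2_onset)
    expect_true(all(d >= 1 & d <= 2))
    expect_true(validObject(scen[[a]]$dataset))
  }
  ## ground truth reports injected latencies in the intended area bands
  gtM <- scen$MFG$groundTruth
  gtP <- scen$PCG$groundTruth
  audM <- gtM[gtM$trigger == "cue1_onset", ]
  expect_true(all(audM$onset_latency >= 0.15 & audM$onset_latency <= 0.21))
  tgtP <- gtP[gtP$trigger == "cue2_onset", ]
  expect_true(all(tgtP$onset_latency >= 0.39 & tgtP$onset_latency <= 0.45))
})

test_that("empirical PSTH converges to the generative rate", {
  profiles <- list(tuningProfile("u1", 10, list(
    responseComponent("cue1_onset", 3, 0.2, 0.4, tasks = "AV"))))
  psth_err <- function(n, seed) {
    ds <- simulateEnsemble(scenarioConfig(nUnits = 1, nTrials = c(AV = n),
                                          profiles = profiles,
                                          seed = seed))$dataset
    tr <- trialTable(ds)
    bins <- seq(0, 0.8, by = 0.1)
    emp <- sapply(head(bins, -1), function(s)
      mean(vapply(seq_len(nrow(tr)), function(i)
        countInWindow(spikeTrain(ds, tr$trial_id[i], "u1"),
                      tr$cue1_onset[i] + s, 0.1), numeric(1))) / 0.1)
    truth <- c(10, 10, 30, 30, 30, 30, 10, 10)
    max(abs(emp - truth))
  }
  e_small <- psth_err(60, 3)
  e_large <- psth_err(600, 4)
  expect_lt(e_large, e_small)      # sup-norm error shrinks with trials
  expect_lt(e_large, 2.5)          # and is close at 600 trials
})
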