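test_that("embedding is deterministic, order-preserving, and validated", {
  ds <- nullEnsemble(2, 20, seed = 41)
  fs <- pairwiseFeatures(ds, "cue1_onset", 0.2, 0.7)
  m1 <- ssimsEmbed(fs, seed = 9)
  m2 <- ssimsEmbed(fs, seed = 9)
  expect_identical(coordinates(m1), coordinates(m2))
  expect_equal(m1@trials, fs@trials)
  expect_equal(m1@settings$nDims, 2)
  expect_error(ssimsEmbed(fs, perplexity = 10, seed = 1), "maximum")
})

test_that("separated firing patterns cluster; homogeneous trials do not", {
  ## strong two-group structure: unit bursts only on red trials
  ds <- boxcarEnsemble(3, 30, onset = 0.1, duration = 0.6, seed = 17,
                       conditionKey = "auditory_cue",
                       gains = c(red = 8, blue = 1), baseline = 3)
  fs <- pairwiseFeatures(ds, "cue1_onset", 0.1, 0.7)
  lab <- trialTable(ds)$auditory_cue
  map <- ssimsEmbed(fs, seed = 3)
  expect_gt(meanSilhouette(coordinates(map), lab), 0.5)

  ## nearest-centroid classification on the map beats chance 1/2
  co <- coordinates(map)
  cent <- rbind(colMeans(co[lab == "red", ]), colMeans(co[lab == "blue", ]))
  pred <- c("red", "blue")[apply(co, 1, function(p)
    which.min(colSums((t(cent) - p)^2)))]
  acc <- mean(pred == lab)
  expect_lt(binom.test(sum(pred == lab), length(lab), 0.5,
                       alternative = "greater")$p.value, 0.01)

  ## null ensemble: labels carry no structure, silhouette near zero
  ds0 <- nullEnsemble(3, 30, seed = 18)
  fs0 <- pairwiseFeatures(ds0, "cue1_onset", 0.1, 0.7)
  lab0 <- trialTable(ds0)$auditory_cue
  sil <- vapply(1:20, function(s)
    meanSilhouette(coordinates(ssimsEmbed(fs0, seed = s)), lab0), numeric(1))
  expect_true(all(abs(sil) < 0.2))
})

test_that("within/between statistics normalize by the within median", {
  set.seed(31)
  ## two well-separated unit-spread clouds
  co <- rbind(matrix(rnorm(40), ncol = 2),
              matrix(rnorm(40) + 10, ncol = 2))
  lab <- rep(c("a", "b"), each = 20)
  st <- categoryDistanceStats(co, lab)
  expect_equal(median(st@normalizedWithin), 1)
  expect_gt(median(st@normalizedBetween), 1)
  expect_lt(st@kwP, 0.001)
  expect_false(st@degenerate)

  ## invariance under rigid motion and uniform scaling
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  st2 <- categoryDistanceStats(3.7 * co %*% R + 5, lab)
  expect_equal(st2@normalizedBetween, st@normalizedBetween, tolerance = 1e-9)
  expect_equal(st2@normalizedWithin, st@normalizedWithin, tolerance = 1e-9)

  ## permuted labels on the same cloud: typically non-significant, median ~ 1
  ps <- replicate(100, {
    s <- categoryDistanceStats(co, sample(lab))
    c(s@kwP, median(s@normalizedBetween))
  })
  expect_gte(mean(ps[1, ] >= 0.05), 0.9)
  expect_lt(abs(median(ps[2, ]) - 1), 0.1)

  ## degenerate geometry: coincident within-category points are flagged
  co0 <- rbind(matrix(0, 5, 2), matrix(1, 5, 2))
  st0 <- categoryDistanceStats(co0, rep(c("a", "b"), each = 5))
  expect_true(st0@degenerate)
  expect_true(all(is.na(st0@normalizedBetween)))

  ## a category with a single trial has no within pairs
  expect_error(categoryDistanceStats(co, c("solo", lab[-1])), "< 2 trials")
})

test_that("session pooling combines per-session normalized distances", {
  set.seed(33)
  mk <- function(sep, scale) {
    co <- scale * rbind(matrix(rnorm(30), ncol = 2),
                        matrix(rnorm(30) + sep, ncol = 2))
    categoryDistanceStats(co, rep(c("a", "b"), each = 15))
  }
  ## two sessions with very different map scales but the same structure
  pooled <- poolCategoryDistanceStats(list(mk(6, 1), mk(6, 50)))
  expect_gt(median(pooled@normalizedBetween), 1)
  expect_lt(pooled@kwP, 0.001)
  ## per-session normalization removed the scale difference
  expect_lt(abs(median(pooled@normalizedWithin) - 1), 0.05)
  ## no structure in either session: pooled statistic stays null
  null1 <- categoryDistanceStats(matrix(rnorm(60), ncol = 2),
                                 rep(c("a", "b"), each = 15))
  null2 <- categoryDistanceStats(50 * matrix(rnorm(60), ncol = 2),
                                 rep(c("a", "b"), each = 15))
  pooled0 <- poolCategoryDistanceStats(list(null1, null2))
  expect_lt(abs(median(pooled0@normalizedBetween) - 1), 0.25)
})

test_that("context contrast separates task-modulated aural responses", {
  ## MFG-like toy: responds to sounds in both contexts, but more strongly in
  ## the task context
  profiles <- lapply(1:4, function(i) tuningProfile(sprintf("u%d", i), 8, list(
    responseComponent("cue1_onset", 4, 0.15, 0.6, tasks = "AV"),
    responseComponent("stimulus_onset", 1.8, 0.15, 0.6, tasks = "passive"))))
  sim <- simulateEnsemble(scenarioConfig(
    area = "MFG", nUnits = 4, nTrials = c(AV = 20, passive = 24),
    profiles = profiles, seed = 51))$dataset
  dsT <- filterTrials(sim, function(tr) tr$task == "AV")
  dsP <- filterTrials(sim, function(tr) tr$task == "passive")
  cc <- contextContrast(dsT, dsP, seed = 4)
  expect_lt(cc$context@kwP, 0.001)
  expect_gt(median(cc$context@normalizedBetween), 1)
  ## evoked vs baseline separates in both contexts here (both respond)
  expect_lt(cc$taskVsBaseline@kwP, 0.001)

  ## identical features supplied as both contexts: contrast ~ 1, n.s.
  cc0 <- contextContrast(dsT, dsT, seed = 5)
  expect_lt(abs(median(cc0$context@normalizedBetween) - 1), 0.2)
  expect_gt(cc0$context@kwP, 0.001)

  ## unit mismatch is an error
  dsP2 <- dsP
  dsP2@units <- dsP2@units[-1]
  dsP2@spikes <- lapply(dsP2@spikes, function(s) s[-1])
  expect_error(contextContrast(dsT, dsP2), "unit set")
})
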