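---
title: "Spike-train similarity, tuning, latency and decoding analysis for cued action planning"
author: "planspike authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{planspike methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planspike)
```

## The scientific problem

Instructed-delay cued-movement experiments separate the arrival of
action-relevant information from movement execution: a participant (or an
intracortical brain-computer-interface user) is told *what* to do through one
or more sensory cues, waits through enforced delays, and acts only at a go
signal.  Simultaneous microelectrode recordings from two cortical sites — a
premotor-like site on the middle frontal gyrus (MFG) and a motor site on the
precentral gyrus (PCG) — make it possible to ask *when* each area starts
carrying information about the upcoming action, and *which* cue modality
engages it.

`planspike` implements the complete single-unit and ensemble analysis chain
for this question, operating on trial-aligned spike times:

1. **Victor–Purpura (VP) spike-train edit distance** with its temporal
   precision calibration, and per-unit pairwise distance matrices over trials.
2. **Spike-train similarity space (SSIMS)**: a t-SNE embedding of the
   concatenated distance features, with a normalized within/between-category
   distance statistic to quantify whether trials of a common condition
   cluster.
3. **Sliding-window responsive/selective classification** of single units
   against a pre-cue baseline (Kruskal–Wallis, p < 0.01).
4. **Response-onset latency estimation** from runs of significant bins, with
   group comparisons between areas.
5. **Fixed-window aural responsiveness / selectivity / context-modulation
   tests** contrasting task and passive-listening contexts.
6. **Sliding-window population decoding** (linear SVM, stratified 5-fold
   cross-validation) with label-permutation chance bands.
7. A **synthetic ensemble generator** with known ground truth, used by every
   test in the package.

## Task model

Four trial structures are supported, each with its own required event
sequence:

* **AV**: baseline (1–2 s) → auditory cue → partial-information delay
  (1–2 s) → visual cue → full-information delay (1–2 s) → go.
* **VA**: the same with cue order reversed.
* **A+V**: both cues simultaneously, then a single delay and go.
* **passive**: a sound is played; no behavioural requirement.

Each of four targets is the unique combination of an auditory colour cue
("red"/"blue") and a visual shape cue (circle/square), so a single cue
carries partial target information and the second cue completes it.  Spike
times are stored on a session clock; every analysis aligns to a named trial
event on demand, so one dataset serves analyses of any transition.  Windows
are half-open `[start, start + width)` — a spike on the right edge belongs to
the next window, which makes counts over a partition add exactly.  Time 0 is
the alignment event and negative times are pre-event.  Unsuccessful and
false-start trials are retained by the loader and removed by an explicit
`successfulTrials()` call, so passive data (where failure is undefined) reuse
the same path.

## The Victor–Purpura metric and its calibration

The VP distance is the minimal total cost of editing one spike train into
another with three operations: insert a spike (cost 1), delete a spike (cost
1), move a spike by $\Delta t$ (cost $q\,\Delta t$).  The dynamic programme

$$D_{i,j} = \min\big(D_{i-1,j} + 1,\; D_{i,j-1} + 1,\;
  D_{i-1,j-1} + q\,|a_i - b_j|\big)$$

is implemented in C++ because the pipeline computes full trials × trials
matrices for every unit.  An independent brute-force oracle (exhaustive
enumeration of monotone partial matchings) is part of the package and is held
to exact agreement with the dynamic programme in the tests.

$q$ is calibrated from an *equivalence shift* $\Delta_{eq}$: the shift
duration at which moving a spike costs the same as deleting it and inserting
another, giving $q = 2/\Delta_{eq}$.  The default $\Delta_{eq} = 100$ ms
(q = 20/s) makes the metric sensitive to spike timing at the ~100 ms scale;
at $q \to 0$ it degenerates to a spike-count difference.  A reading of the
equivalence as "replacement cost 1" would halve $q$; the standard convention
(cost 2) is used.

Distance features for the embedding are the per-unit distance matrices
joined horizontally: trial $i$ is described by its distance to every trial,
for every unit (a trials × (trials·units) matrix).  Summing per-unit
matrices instead would discard which unit carries the dissimilarity; the
concatenation convention preserves it.

## SSIMS embedding and the distance statistic

t-SNE reduces the concatenated feature rows (treated as Euclidean vectors) to
`nDims = 2`.  The embedding hyper-parameters are not dictated by the method
itself, so they are package choices, recorded in every `SSIMSMap`:
perplexity 30 capped strictly below (trials − 1)/3, 1000 iterations, random
initialization from a fixed seed.  Runs are deterministic given the seed.

Cluster quality is quantified without reference to the embedding's axes:
pairwise Euclidean distances among points are split into *within*-category
and *between*-category pairs and both are divided by the within-category
median.  A normalized between value of 1 means "no more separated than a
typical same-category pair"; values well above 1 indicate category structure.
A Kruskal–Wallis test compares the two normalized distributions.  When
several sessions are pooled, each session is normalized by its own within
median before pooling, which removes session-scale differences.  If the
within-median is exactly 0 (coincident points) the statistic is undefined;
the result is flagged `degenerate` rather than dividing by zero.

For the context-dependence analysis, task-evoked epochs, passive-evoked
epochs, and the pre-stimulus baseline epochs of the *same trials* are
embedded in one joint map, and the same statistic is applied to the
context labels (task vs passive) and to evoked-vs-baseline within each
context.  Using the same trials' pre-stimulus windows as the baseline
category keeps the ensemble and trial count matched.

## Sliding-window tuning tests

A unit is **responsive** in a window if its per-trial rates differ from the
per-trial baseline rates (300 ms preceding the first cue), and **selective**
if rates differ across cued targets, both by Kruskal–Wallis at p < 0.01 on
300 ms windows stepped across the transition of interest.  Two conventions
the package fixes explicitly:

* The baseline is always the 300 ms before the trial's *first* cue, also when
  windows are aligned to a later cue.  Re-baselining at each cue would fold
  sustained delay activity into the null and mask it.
* No multiple-testing correction is applied across sliding windows — the
  output is a per-window *fraction of units*, not a per-unit claim.
  Bonferroni correction is applied exactly where the aural tests specify it
  (across stimuli, and across the two task cues in the context test).

Because delays vary 1–2 s, windows are analysed per aligned epoch with grids
that end before the earliest possible next event (0.8 s used throughout),
rather than warping time.

With all counts equal in both groups the rank test carries no evidence and
p = 1 is returned by convention.  On discrete Poisson counts the
Kruskal–Wallis test is conservative, never anticonservative; the test suite
verifies per-window null rejection ≤ α + 3·SE on 200 null units.

The fixed-window aural tests compare 500 ms pre-stimulus counts with a
500 ms post-stimulus window starting 200 ms (MFG) or 400 ms (PCG) after
onset — offsets chosen to centre the window on each area's typical response
peak — with Bonferroni correction over the stimuli tested.

## Onset latency

The baseline sample pools spike counts of the eight non-overlapping 100 ms
bins in −800..0 ms across trials (8·n values).  Each 100 ms post-cue bin,
stepped by 20 ms across 0..800 ms, is tested against this pooled sample;
response onset is the midpoint of the first bin of the *earliest* run of
three consecutive significant bins ("consecutive" in the 20 ms-stepped
sequence, the only bin sequence defined post-cue).  Analysis stops at 800 ms
to avoid anticipatory activity.  Estimates are therefore quantized to
{50, 70, 90, …} ms; with bins starting at 0 the minimum reachable estimate
is 50 ms, so the exclusion rule for estimates below 40 ms cannot fire under
this convention — it is implemented as a safeguard anyway and its triggering
is logged in the result.  The procedure runs separately per cue type (two auditory cues in
AV, two visual cues in VA, four audio-visual combinations in A+V) and the
unit's latency is the minimum across cue types, so units selective for one
cue are not averaged out.

Group latency distributions are compared with Kruskal–Wallis; the median
difference is reported with the convention "positive = first group earlier".

## Decoding

Features are per-trial mean rates of all units in a 300 ms window; labels are
the decoded condition.  The classifier is a linear maximum-margin SVM
(libsvm through `e1071`; margin penalty 1.0 by default, configurable),
multiclass through exhaustive one-vs-one coding (for 2 classes a
single binary machine).  Folds are stratified, drawn once per run from the
seed and reused across windows so the time course is comparable.  Feature
standardization is fit on training folds only; the shuffled-label
calibration test would expose any leakage.  Chance bands are the 2.5/97.5%
quantiles of accuracies under label permutations: each permutation shuffles
labels once and reuses the shuffle across windows, preserving the temporal
coherence of the null.  The full-scale default is 10,000 permutations; desk
runs use 200, which the band quantiles tolerate.

## The synthetic generator

Units are inhomogeneous Poisson processes.  A unit's intensity is its
baseline rate multiplied by the gains of all active response components; a
component is locked to a trial event, gated by task variant, keyed by a
condition label (so unequal gains inject selectivity), and shaped as a boxcar
or an alpha transient ($1 + (g-1)(s/\tau_\alpha)e^{1-s/\tau_\alpha}$,
$\tau_\alpha =$ duration/4).  Spikes are drawn by thinning against the exact
per-trial maximum of the intensity; the tests check the time-rescaling
theorem (rescaled inter-spike intervals are unit-rate exponential) and that
the draw law is invariant to inflating the dominating bound.

Deliberate simplifications: pure Poisson firing (no refractoriness) because
every downstream statistic is rank- or count-based; multiplicative gains so
baseline heterogeneity and modulation depth decouple; no correlated noise
across units; stationary baselines.  Passing tests on this generator
therefore demonstrate the *analysis chain's* correctness and calibration —
they do not certify performance on real recordings with bursting, shared
variability, or non-stationarity.

The reference scenario (`multimodalScenario()`) fixes the study conditions:
40 units per area, 72 trials per task variant and 144 passive trials
(the recorded sessions ran ~40–70 units and ~270 trials across the three
variants), delays uniform on 1–2 s, and two area profiles:

* *MFG-like*: 50% of units respond to auditory cue onsets with latencies
  uniform on 150–210 ms (median 180 ms); half of those carry unequal gains
  for the two auditory cues (selective); 24% of all units also respond
  non-selectively and more weakly (gain 1.8 vs 3–3.5) to passive sounds;
  no response to visual cues; a third of units are non-selectively active
  after the go cue.
* *PCG-like*: 70% of units respond with target-dependent gains (preferred
  target 4, others 1.3) only after the final informative cue, latencies
  uniform on 390–450 ms (median 420 ms), persisting selectively through the
  go phase; no passive response.

The 420 − 180 = 240 ms latency gap is the injected ground truth for the
recovery tests.  No quantitative modulation depths are available for the
recorded data, so gains were chosen once to make the qualitative
phenomenology detectable at these trial counts, and are not adjusted
thereafter.

Randomness is governed by a single integer seed per simulation call through
R's own RNG (the generator saves and restores the caller's RNG state); a
counter-based stream with per-trial sub-streams was considered and dropped
because base R provides none and determinism-given-seed is the contract that
matters.

## Numerical and design decisions

* All times in seconds, double precision; half-open windows everywhere.
* VP distances in double precision; each per-unit matrix computed once per
  epoch and reused.
* Default VP epoch: 500 ms starting 200 ms (MFG) / 400 ms (PCG) after cue.
* Kruskal–Wallis handles ties by mid-ranks with the standard correction
  (base R `kruskal.test`); a two-group KW is equivalent to a rank-sum test
  up to tie handling and is used verbatim for consistency.
* Sliding-window and decoding grids in the packaged analyses use 300 ms
  windows with 40 ms steps and 200 permutations; these are the desk-scale
  problem sizes stated for every simulation-based test, chosen so the whole
  suite completes comfortably on one CPU.  The method's canonical full-scale
  settings (20 ms steps, 10,000 permutations) are the `scale = "full"`
  pipeline defaults.
* `runPipeline()` derives per-stage behaviour from one seed and records it,
  with all tables written as CSV plus a JSON manifest.

## Known limitations

* t-SNE is the only embedding offered; the statistic consumes any coordinate
  matrix, so alternative embeddings can be evaluated externally.
* The latency estimator assumes rate increases lasting ≥ the bin width;
  brief (<100 ms) or purely suppressive responses are detected weakly (a
  two-sided rank test does flag suppression, but the scenario injects none).
* Variable delays are handled by truncation at the shortest epoch, not time
  warping.
* The generator does not model the eye-movement effector conditions, local
  field potentials, or vendor acquisition formats; the documented CSV/YAML
  directory format is the only interchange format.

## A worked example

```{r example, eval = FALSE}
scen <- multimodalScenario(seed = 1, nUnits = 20, nTrials = 40, nPassive = 60)
mfg <- scen$MFG$dataset
av <- filterTrials(mfg, function(tr) tr$task == "AV")

## tuning fractions after the auditory cue
g <- windowGrid(-0.3, 0.8, 0.3, 0.04)
res <- do.call(rbind, lapply(unitIds(av), function(u)
  classifyResponsive(av, u, "cue1_onset", g)))
ensembleFractionTimecourse(res)

## SSIMS separation of the two auditory cues
f <- pairwiseFeatures(av, "cue1_onset", 0.2, 0.7)
st <- categoryDistanceStats(ssimsEmbed(f, seed = 1),
                            trialTable(av)$auditory_cue)
st
```
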