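---
title: "Deciding whether observed and executed actions share a neural code"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding whether observed and executed actions share a neural code}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the design

Premotor mirror neurons discharge both when a subject performs an object
manipulation and when it watches another individual perform it. Whether the
*mapping from action to discharge rate* — the action code — is the same in
the two contexts is the question this package operationalizes. The paired
design has two tasks (execution, observation) times three actions (lift,
twist, shift), with at least eight valid trials per each of the six
conditions. A trial is described by eight sensor events: start-button press
(BPR, the per-trial time origin), LED cue onset (LED), start-button release
(RLS), object touch (TCH), object-movement onset (MOV), hold onset (HLD),
reward (REW) and withdrawal (WDR).

The pipeline answers three nested questions, each with its own module:

1. Does the neuron respond to the task at all (mirror-neuron screen)?
2. Does its rate depend on the action, per time bin and task
   (action-coding table)?
3. Where it codes in both tasks, is the code *shared* (three single-cell
   methods, an independence permutation null, an accuracy-angle boundary
   analysis, segment statistics, and population decoding)?

## Relative time: 24 quartile bins

Event timing varies across trials, actions and tasks, so absolute peri-event
time is not comparable. Each of the six inter-event epochs (BPR–LED, LED–RLS,
RLS–TCH, TCH–HLD, HLD–REW, REW–WDR; MOV is used only by the screen) is
divided into four equal-duration quartile bins, giving 24 bins per trial.
Bins are half-open `[a, b)` — a spike exactly on an interior edge belongs to
the bin on its right — so no spike is counted twice, and
`sum(rate_i * width_i)` reproduces the trial's spike count exactly. Rates are
expressed in Hz; any strictly monotone common rescaling would leave the rank
tests untouched, and the classifier sees the same unit in train and test.
The *action period* is bins 9–20 (RLS through REW), 12 bins; all shared-code
decisions are confined to it.

## Mirror-neuron screen

Five windows per trial — baseline `[LED-750, LED-250)` (truncated at BPR if
the cue came early, with the rate computed over the actually covered
duration), approach `[RLS, TCH)`, manipulation-I `[TCH, MOV)`,
manipulation-II `[MOV, HLD)`, hold `[HLD, HLD+150)` — feed a Friedman test
(trials as blocks, windows as the repeated factor) per task and action.
A *motor* (resp. *visual*) response is a significant modulation for at least
one action during execution (resp. observation) at `alpha/3` (Bonferroni
over the three actions); a mirror neuron has both. No agreement of epoch or
direction between tasks is required. Neurons with fewer than eight valid
trials in any condition are excluded with a recorded reason.

## Action coding per bin

Per neuron, bin (all 24) and task, a Kruskal–Wallis test across the three
actions asks whether the rate depends on the action. Each task forms one
Benjamini–Hochberg family of size `n_neurons x 24` — deliberately the whole
grid, even though downstream analyses use only the 12 action-period bins.
Undefined tests (a bin with no trials) are dropped from the family and
counted. Derived flags per action-period bin: `exe_coding`, `obs_coding`,
`both`, `obs_only`.

## Three shared-code criteria

All three run only on *both-coding* bins, and their BH families are counted
across the whole population:

* **Same discharge** — per bin and action, a two-sided Wilcoxon rank-sum
  test (normal approximation, midrank tie correction, 0.5 continuity
  correction) compares execution against observation rates; family
  `both-bins x 3`. Shared means *no* action differs: the strictest,
  "perfect-code" criterion, sensitive even to a pure gain change.
* **Same preference** — the two per-task mean-rate triplets are reduced to
  indicator vectors of the preferred action (positive polarity: divide by
  the maximum and floor; negative polarity: subtract the maximum, divide by
  the signed minimum and floor), unit-normalized, and multiplied. An index
  of 1 means identical preference. Trials are bootstrapped within each of
  the six conditions (1000 resamples); the p-value is the fraction of
  resamples with an index below 1; family `both-bins x 2` for the two
  polarities. Insensitive to gain, sensitive only to which action is most
  (or least) driving.
* **Cross-task classification (LDA)** — a diagonal linear discriminant
  classifier (class means plus one pooled per-feature variance) is trained
  on execution trials and tested on observation trials of the same bin,
  with eight-fold cross validation inside a 1000-resample bootstrap; the
  p-value is the fraction of resamples with accuracy at or below chance
  (1/3); family `both-bins`. Uses raw rates with no offset correction,
  rescaling or ranking.

Bins coding only during observation are labeled `obs_only`; they cannot
carry a shared code by definition.

### Classifier geometry

The per-condition trial count is adjusted to `T`, the largest multiple of
eight at or below the minimum across all six conditions (neurons with
`T < 8` are excluded from classification). Per bootstrap resample, `T`
trials are drawn with replacement per condition and split into eight folds;
the classifier is fit on the training task's remaining 7/8 and tested on
the held-out fold of the *test* task. Forming the folds per condition on
both tasks jointly keeps fold sizes identical across the four modes (e2e,
o2o, e2o, o2e); a `train_folds = FALSE` switch instead trains on all of the
training task's resampled trials, for users who prefer the alternative
reading of the cross-task geometry. Two consequences of resampling with
replacement are accepted as part of the contract rather than corrected:
the same original trial can appear in both a training and a test fold, so
*within-task* accuracies on pure-noise data sit slightly above chance
(strongly so for high-dimensional population decoding — visible as the
above-chance pre-cue within-task accuracy typical of such analyses), while
cross-task accuracies are unaffected; and the bootstrap p-value is a plain
fraction with no +1 smoothing, so its minimum is exactly 0.

With one feature, balanced classes and a single pooled variance, the
diagonal-LDA argmax reduces algebraically to the nearest-class-mean rule;
the vectorized engines exploit this (and the analogous array algebra for
populations) and are verified against explicit `diag_lda_fit()` /
`diag_lda_predict()` loops in the test suite. Ties go to the lowest class
index; the pooled variance is floored at `1e-9` Hz² so silent bins cannot
produce degenerate densities.

## Independence permutation null

The null hypothesis is that observation coding is distributed over the
population independently of execution coding. Each of the 250 resamples
re-pairs every neuron's execution data with a *different* neuron's
observation data — a fixed-point-free permutation (derangement), read
literally from "a different neuron"; uniqueness across resamples is enforced
by hashing, and the subfactorial bounds the request for small populations.
Within-task data are untouched, so the per-task coding flags are computed
once and only the pairing varies; each resample reruns the both-bin
bookkeeping and the requested shared-code method. The expensive bootstraps
inside the null default to 200 resamples (switchable to 1000); the null
distributions of counts are summarized by central 95% intervals. The
permutation is pooled over the whole population: the synthetic data carry
no session or animal structure that would motivate stratification.

## Accuracy-angle boundary analysis

For every (neuron, action-period bin), the e2o and o2o bootstrap-mean
accuracies relative to chance (in percentage points) form a point;
`atan2(e2o_rel, o2o_rel)` is its angle. 45° is the unity line (both
classifiers equally good — shared-like), 0° the zero line (e2o at chance —
non-shared-like); points with both coordinates exactly 0 are undefined and
counted. Points are filtered by increasingly strict thresholds on the o2o
accuracy (5–15% above chance, 11 thresholds, strict inequality), and the
angle histogram is fit by one- and two-Gaussian curves
(`sum a_j exp(-((x-b_j)/c_j)^2)`, Levenberg–Marquardt nonlinear least
squares). Numerical choices, made explicit because the procedure leaves
them open:

* histogram bin width 2° over (−90°, 90°] (fits on counts, not densities);
  a sensitivity test shows the boundary moves by < 3° between 1° and 5°
  widths;
* initial guesses: one-Gaussian — maximum count, circular-mean angle, 20°
  width; two-Gaussian — centers at the two reference lines (0° and 45°),
  15° widths, local histogram heights as amplitudes;
* a two-Gaussian fit succeeds only with two distinct modes (centers ≥ 5°
  apart, both amplitudes positive); failures are retried with centers
  jittered ±10°, budget 50, and per-resample failures are counted, with an
  abort above a 10% failure rate;
* fits require at least 30 points above threshold;
* adjusted R² uses `p = 3k` parameters; peaks and the trough (boundary)
  between the two fitted centers are read off a 0.1° grid of the fitted
  curve.

95% CIs for adjusted R², both peaks and the boundary come from resampling
the *full* point set 1000 times with replacement and re-filtering per
threshold. The *average boundary angle* is the mean of the 11 per-threshold
boundaries of the original fits. The *threshold method* then labels every
bin with o2o accuracy more than 10% above chance as shared if its angle is
at or above the average boundary, else non-shared — no single-cell test
involved.

## Segments and populations

Maximal runs of consecutive action-period bins with the same code type are
*action segments*; obs-only bins count as non-shared, uncoded bins break
runs. With 12 bins there are `12*13/2 = 78` possible (start, duration)
segments; histograms are reported absolutely and normalized by the total
bin count of each code type.

Population decoding uses one feature per neuron. Because neurons were not
recorded simultaneously, pseudo-trials are assembled per bootstrap
resample: each neuron independently contributes eight sampled trials per
condition (the floor that every screened neuron satisfies), concatenated by
index — noise correlations are deliberately not modeled, and the pairing is
redrawn per resample. Subpopulations are selected from the single-cell
labels (`any_shared`, `only_shared_threshold`, `per_bin_shared` with its
per-bin variable size); population intervals are central 90% (the
population-analysis convention), all others 95%.

## The synthetic generator

The generator exists so that every stage is testable end to end without
recorded data. What it emulates:

* the event-duration structure per task and action: each inter-event epoch
  duration is drawn uniformly between the central-95% bounds observed for
  the monkey (execution) and the human actor (observation) — only bounds
  and means of the real durations are known, and a uniform over the bounds
  is the simplest model consistent with both (its mean lands within a few
  percent of the printed means, e.g. ≈ 568 ms for the 0.3–0.8 s
  hold-to-reward interval). MOV is placed uniformly inside TCH–HLD, which
  the duration table does not separate;
* Poisson spiking with rates constant within each quartile bin — matching
  the 24-bin analysis resolution;
* four planted coding profiles: `shared` (identical action→rate map in
  both tasks), `non_shared` (the map cyclically permuted between tasks,
  guaranteeing coding in both with a different preference), `obs_only`,
  `non_coding`;
* an action-independent rate elevation across the action period
  (`rate_modulation`, default 10 Hz on a 10 Hz base) so that simulated
  neurons are task-responsive and pass the Friedman screen, as recorded
  mirror neurons by construction do; setting it to 0 yields an unmodulated
  population for screening-calibration tests;
* per-neuron coding *segments*: by default the action effect (default
  +20 Hz on the preferred action, i.e. 3x base) occupies one contiguous
  run of 1–6 action-period bins (short durations more probable, uniform
  start). This mirrors the empirical finding that coding occupies short
  segments, and it is what gives the independence null its bite: if every
  coding neuron coded in all 12 bins with one fixed preference, a
  derangement partner would match by chance in a third of the pairs and
  the planted shared fraction would not separate from the null. An
  explicit `coding_bins` vector overrides the default for power and
  fixture tests.

What it does not emulate — and what passing tests therefore do not show
about recordings: non-Poisson spiking statistics (burstiness, refractory
periods), rate dynamics within bins, noise correlations between neurons or
across tasks, session/animal structure, drifting preferences within a
segment, eye movements or kinematics, and any dependence of the spike rate
on the actual event timing beyond the bin structure.

Determinism: the population seed drives every draw; identical
configurations produce byte-identical CSV exports. Pipeline stages consume
child seeds derived from the master seed, so end-to-end runs are exactly
reproducible.

## Problem sizes used by the shipped checks

The test suite and the acceptance script validate the pipeline at sizes
chosen to exercise every stage meaningfully: type-I calibration on 177
non-coding neurons at 16 trials per condition against 250-permutation
nulls; recovery of a planted 20/50/10/20 mixture on 60 neurons at 64 trials
per condition with full-size (1000-resample) method bootstraps and a
250-permutation null at the reduced inner bootstrap; angle-mixture recovery
on 2000 points with 200 bootstrap refits per threshold; and a 60-neuron
end-to-end pipeline run executed twice to confirm determinism. Sample sizes
per condition (8–64) span the range the trial-count floor and the
cross-validation geometry allow.

## Known limitations

* The preference bootstrap treats a degenerate resample in which all three
  mean rates tie (possible only in nearly silent bins) as "all actions
  preferred", which is conservative toward sharedness but occurs with
  vanishing probability off the zero-rate boundary; flooring uses a 1e-12
  tolerance against `0.999...` division artifacts.
* Exact rank-test p-values are not implemented; the chi-square and normal
  approximations are used throughout, appropriate at the ≥ 8-trial floor.
  Borderline p-values can shift between tie/continuity conventions; the
  shipped conventions are stated above and verified against base R's
  implementations.
* The baseline window can truncate at trial start for early cues; its rate
  then uses the covered duration only.
* The two-Gaussian fit assumes at most two angle clusters; more structured
  angle distributions would need a different model.
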