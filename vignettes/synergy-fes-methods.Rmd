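---
title: "Muscle-synergy assessment and synergy-based FES design: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle-synergy assessment and synergy-based FES design: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergait)
```

## The model

`synergait` treats multi-channel gait EMG as the output of a low-dimensional
modular controller. Writing the time- and amplitude-normalized envelopes of
`N` muscles over `T` samples as a nonnegative matrix `M` (N × T), the model
is the nonnegative factorization

    M ≈ W · H,      W ≥ 0 (N × J),   H ≥ 0 (J × T),

where each column of `W` is a *muscle synergy* — a fixed weighting of
muscles — and the matching row of `H` its activation profile over the gait
cycle. For healthy walking four synergies carry the main biomechanical
functions: weight acceptance (WA, hip/knee extensors in early stance), push
off (PO, plantar-flexors in late stance), foot clearance (FC, rectus
femoris and tibialis anterior around heel strike and early swing) and leg
deceleration (LD, hamstrings in late swing wrapping into early stance).

The assumptions worth keeping in mind:

* **Nonnegativity is structural.** Envelopes, weights and activations are
  all nonnegative; the factorization is fitted with Lee–Seung
  multiplicative updates, which preserve nonnegativity and never increase
  the squared reconstruction error.
* **Synergies are fixed within a session.** The same `W` is assumed to act
  on every stride; stride-to-stride variation is carried by `H` (extraction
  runs on the 20 concatenated 100-point strides, so `H` has per-stride
  temporal components whose mean is the cycle profile).
* **Impairment is deviation from a healthy template**, not poor fit per se:
  a patient's envelopes are *reconstructed* in the healthy synergy space
  (NNR, one factor frozen) and scored against the healthy template.

## Fitting and model order

`synergy_nmf()` runs seeded multiplicative updates from uniform random
starts (default 20 restarts, 1000 iterations, relative-error tolerance
1e-6) and keeps the lowest-error restart; with a fixed seed the fit is
bit-reproducible. Weights are returned unit-normalized, the scaling
absorbed into `H` so `W·H` is unchanged. Fit quality is the variability
accounted for, `VAF = 1 − SSE/SST` with *uncentered* SST, overall and per
muscle; the uncentered convention matches the criterion usually used with
this model family, and a zero-SST muscle yields `NA` rather than a silent
zero.

`select_model_order()` ascends J and stops at the first J with total
VAF > 0.90, or for which adding a synergy improves no single muscle's VAF
by more than 5%. Both factorizations involved in the second clause are
cached; if no J qualifies up to `j_max` the function warns and returns
`j_max`.

## NNR: projecting a patient onto healthy synergies

Two reconstructions are run against the cohort template, each freezing one
factor and updating the other multiplicatively (denominator guarded by
1e-12 so 0/0 never occurs; the frozen factor is returned bit-identical):

* fixed `W_healthy` (unit-norm columns required), free `H`: yields
  per-stride activation profiles and their mean cycle;
* fixed `H_healthy`, free `W`: the one-cycle healthy profiles are tiled
  across the patient's strides (the minimal embedding consistent with a
  20-cycle envelope matrix), yielding the patient's weights.

The four impairment metrics then use each reconstruction for what it
frees: weight **similarity** (cosine) comes from the fixed-H fit;
**correlation** (maximal centered circular cross-correlation), **T-lag**
(`1 − |lag|/100`, lag in percent of cycle at the correlation maximum, ties
broken toward the smaller |lag|) and **activation duration**
(`1 − |Δduration|/100`) come from the fixed-W fit's mean profile. Duration
is the count of samples strictly above the profile minimum plus 20% of
peak-to-peak amplitude; multi-burst profiles contribute the total time of
all bursts (chosen over first-onset-to-last-offset, and configurable,
because the two-burst FC profile would otherwise count its silent gap as
"active"). A flat profile gets duration 0 with a degeneracy flag.

Thresholds pool each metric's values across healthy subjects *and*
synergies (one threshold per metric, common to all synergies) at
mean − 2·SD (sample SD). A synergy is impaired when at least one metric is
*strictly* below threshold — equality passes. The strict inequality is
load-bearing: a patient value exactly at threshold (it happens; the metrics
are discrete in steps of 0.01 for T-lag and duration) is classified as
within normal limits.

## Stimulation strategy

Target activations are rebuilt from the impaired synergies only,
`E = W[, impaired] · H[impaired, ]`, and each recruited muscle's profile is
rescaled to peak 1 (the stored scale factors make the rescale invertible).
Muscles recruited by no impaired synergy keep an exactly-zero profile and
are never stimulated. Each profile is gated at its minimum + 20% of
peak-to-peak (fatigue management); gating precedes channel grouping, so
channels form over the profiles that will actually be delivered.

Grouping is greedy single-linkage over the gated profiles in muscle order:
a muscle joins the first channel containing a member whose profile cosine
reaches the threshold. The default threshold is **0.98**, and the choice
deserves a note: muscles principally loaded by the *same* synergy have
profile cosines above ~0.94 by construction (any cross-talk of the
realistic ≤ 0.15 magnitude barely moves the cosine), so a lenient threshold
like 0.90 would merge, say, gluteus maximus with vastus medialis, which are
distinct stimulation targets. "Very similar" is therefore implemented as
near-identity: only muscles driven by the same synergies with the same
mixing (hamstrings pair, calf pair) share a channel. The threshold is a
plain argument for electrode layouts that warrant coarser grouping.

Intensities map linearly to pulse width, 0–400 µs (rounded to the
microsecond), at a common 20 Hz; per-channel amplitudes come from clinical
calibration and are carried as configuration, never computed.

## Six-phase warping

IC (initial contact), EC (end contact) and MS (mid-swing) events per leg
define six phases per stride, in fixed cyclic order: paretic double
support (paretic IC → non-paretic EC), non-paretic initial swing (→ MS),
non-paretic terminal swing (→ IC), non-paretic double support (→ paretic
EC), paretic initial swing (→ MS), paretic terminal swing (→ paretic IC).
This boundary table is the unique assignment consistent with the phase
names and the three event types per leg; any out-of-order event raises a
sequence violation naming the expected event rather than resynchronizing
silently.

Each phase's duration estimate is the mean of its last ≤ 5 completed
strides. Warping treats the 100-point template as a cyclic piecewise-linear
function, splits it at six cycle fractions, and resamples segment *i* to
`round(duration_i × rate)` samples over `[c_{i-1}, c_i)` — half-open, so the
join sample belongs to the next segment and a uniform speed change
reproduces exactly the uniform resampling of the whole cycle. Changing one
phase's duration changes only that segment's samples. Warping is causal:
stride *k* uses estimates from strides before *k*; the first stride, with
no history, uses the template proportions scaled to its own observed cycle
time. A phase estimate mapping to zero samples is skipped with a warning.

The default template phase fractions (0.12, 0.19, 0.19, 0.12, 0.19, 0.19)
are textbook symmetric-gait proportions; they are configurable because the
partition of the 100-point cycle into phases is a modeling choice, not a
measured quantity.

## The synthetic-data generator

The generator provides ground truth for every stage. The canonical
template uses raised-cosine bursts (WA centered at 20% of the cycle, width
26; PO at 45, width 26; FC two bursts at 2 and 65; LD at 94, width 24,
wrapping the cycle boundary) and weight supports on the physiological
muscle groups with cross-talk ≤ 0.15; the calf muscles carry exactly zero
weight in FC and LD, so a strategy built from those synergies alone leaves
the calf unstimulated. A healthy cohort adds, per subject, truncated
Gaussian weight noise (SD 0.10, re-normalized), systematic per-synergy
timing shifts (SD 3 points) and burst-width factors (SD 0.20), plus
per-stride timing jitter (SD 2 points) and envelope noise (SD 5% of the
signal peak, clipped at zero). These heterogeneity levels were chosen so
that the pooled healthy metric distributions have realistic spread — with a
near-homogeneous cohort the mean − 2·SD cut lands inside the normal range
and flags healthy subjects, which would defeat the thresholds' purpose.
Stroke-like patients start from the template (not from a cohort member) and
inject deficits: merged synergy pairs (summed re-normalized weights driven
by the union of the bursts), circular lag shifts (negative = early
recruitment), and burst widening about the peak.

What the generator does **not** emulate: electromechanical delay, fatigue
drift within a session, electrode cross-talk between adjacent muscles,
non-stationary noise, and real stride-length variability coupled to speed.
Passing tests therefore demonstrate the pipeline's internal consistency and
its sensitivity to the modeled deficit classes, not performance on recorded
patient EMG.

## Numerical choices

* Zero-phase (forward–backward) Butterworth filtering throughout, doubling
  the effective order, so envelope peaks stay aligned with gait events —
  the timing metrics depend on this. Cut-offs are validated against
  Nyquist, and signals shorter than three filter lengths are rejected.
* Time normalization uses linear interpolation (shape-preserving, no
  overshoot on nonnegative envelopes); stride windows are half-open
  `[IC_i, IC_{i+1})` so samples partition exactly.
* The median over an even number of strides is the mean of the two middle
  values (the standard convention, stated so tests can be exact).
* Representative-stride selection trims a configurable number of strides at
  each end (default 3, covering gait initiation and termination) and takes
  the centered 20.
* Optimal synergy matching is exhaustive over permutations (J ≤ 8), ties
  broken by synergy index order; group averaging unit-normalizes, collapses
  per-stride profiles to the mean cycle, matches, averages element-wise and
  re-normalizes.
* NMF/NNR stop when the relative error decrease falls below tolerance or at
  the iteration cap; error traces are exposed so monotonicity is testable.

## Problem sizes used by the tests

The suite runs entirely on generated data: cohorts of 13 subjects × 20
strides × 8 muscles (envelope matrices 8 × 2000), solver settings
`n_restarts = 5, max_iter = 500, tol = 1e-5` for the stochastic suites,
50 seeds for model-order recovery, 25 for merged-patient order, and 10
patient seeds per condition for the end-to-end closure checks, with the
cohort built once at a fixed seed. These sizes keep the full suite around a
minute while leaving the study conditions (noise level, stride and subject
counts) at their stated values.

## Known limitations

* The circular cross-correlation lag is unstable for multi-modal profiles:
  when a patient's (or a healthy subject's) two-burst FC profile aligns
  better at the other burst, the lag jumps by tens of points. Such outliers
  in the healthy pool inflate the T-lag SD and lower its threshold, making
  T-lag conservative for some cohort draws; the four-metric "any under
  threshold" rule compensates, since timing deficits also depress the
  correlation metric.
* Averaging unit-normalized weights after truncated-at-zero perturbations
  is slightly biased: zero-support entries gain about `SD/√(2π)` and
  re-normalization shrinks large entries correspondingly. At the default
  noise levels the bias is below 0.05 per entry.
* Pooling metric values across synergies (one threshold per metric) is one
  reading of "a threshold common to all muscle synergies"; per-synergy
  thresholds would be the alternative and would change behavior when one
  synergy's metric distribution differs structurally (as FC's duration
  does).
* The session simulator re-plans at phase entry only and does not model
  within-phase corrections for late or early events.
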