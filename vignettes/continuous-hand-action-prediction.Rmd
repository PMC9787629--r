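---
title: "Continuous hand-action prediction with windowed GMM-HMM decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous hand-action prediction with windowed GMM-HMM decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`handhmm` predicts the upcoming gesture in a continuous multi-gesture hand
action from multichannel surface EMG, before the gesture is completed. This
vignette documents the model, the decoder, the synthetic data generator
that stands in for the (private) study recordings, the parameters that
matter, and the design decisions taken where the method's published
description left choices open. Every number mentioned here is computed by
the package's test suite or by `scripts/acceptance.R`; the vignette states
no empirical result beyond those.

## The model and its assumptions

A continuous two-gesture action — front gesture `h_f`, then rear gesture
`h_r` — is modeled as a six-state left-to-right hidden Markov model over
RMS feature vectors. States 1–3 are the front gesture's rising transition,
stabilization, and declining transition; states 4–6 repeat the pattern for
the rear gesture. State 4, the rear gesture's rising transition, is the
*key state*: entering it means the second gesture is starting to form, so
its detection is the earliest moment at which the upcoming gesture can be
announced.

Assumptions this encodes:

* Temporal monotonicity. Phases follow one another and never return, so
  backward transitions are forbidden. "Fully connected left-to-right" is
  ambiguous between "self plus next" and "all forward jumps"; we default to
  the upper-triangular reading (all forward jumps allowed) and expose
  `transitions = "sequential"` for the stricter one. In practice the
  fitted jump probabilities beyond `i -> i+1` are near zero; the choice is
  not load-bearing on synthetic data.
* Transitions are much shorter than stabilization. Rise and decline take a
  few hundred ms of a 2.5 s gesture segment.
* A single diagonal Gaussian per state is enough. Amplitude envelopes per
  channel, not spectra, carry the gesture identity; the RMS feature (100 ms
  windows, 50 ms hop) is the only feature used.
* Every action starts in state 1, so the initial distribution is pinned at
  state one and never re-estimated.

## Decoding: sliding windows with long-term memory

Classic Viterbi needs the whole sequence; an online predictor does not have
it. The decoder therefore processes non-overlapping windows of `T` frames
(default 20 frames = 1 s of signal) and initializes each window's first
frame from the previous window's final per-state maxima:

* first window: `delta_1(i) = pi_i b_i(o_1)`;
* later windows: `delta_1(i) = max_j [delta_prev(j) a_ji] b_i(o_1)`.

Carrying the full `delta` vector across windows makes the windowed
recursion algebraically identical to the full-sequence recursion, so
cumulative per-state maxima — and hence cross-model comparisons — are
exact; the tests assert bit-for-bit equality against classic Viterbi when
one window spans the whole sequence. What windowing does change is
backtracking: paths are backtracked within the current window only (the
first frame carries no backpointer into the previous window). One
consequence is that a state crossing can fall between windows: a path may
enter a window already in state 5 although state 4 was never printed in
any window's path. `detect_key_state()` therefore reports the first frame
*at or beyond* the key state — in a left-to-right topology, being past the
key state implies having crossed it.

All probability arithmetic is in the log domain; delta vectors are never
normalized, so cumulative totals stay comparable across models (all models
consume identical frames from identical start points). Ties in any argmax
break toward the lowest state or model index, making decoding fully
deterministic.

## Prediction and model pruning

Twelve action models (all ordered pairs of four gestures) are organized in
four groups by front gesture. For a two-gesture action, all twelve decode
in parallel; after each window the best model is the one with the highest
cumulative max-path log-probability, and when its window path crosses the
key state an event fires predicting that model's rear gesture.

For longer actions, accumulated probability from previous gestures is
irrelevant to the next transition and drowns it out — the no-pruning
ablation demonstrates exactly this failure. Model pruning repairs it: on
predicting `h_r`, only the group whose front gesture is `h_r` stays
active, every surviving decode state resets to the initial distribution,
and windowing restarts at the key-state frame (the remainder of the fired
window is re-decoded under the new group — the restart is placed at the
state boundary, not the window boundary). After the first event exactly
three models are decoded per window instead of twelve.

One behavior deserves honesty: after the final gesture of a trial, the
closing decline passes through low amplitudes that — to this feature set —
can resemble the start of yet another gesture, so the decoder may flag one
extra, unfalsifiable event at the very end of the data. Evaluation
therefore scores the k-th event against the k-th true transition: a trial
is correct iff every true transition was predicted correctly in order;
per-transition accuracy scores each transition independently; a transition
with no event counts as nongesture (N/G). Trailing extra events are
visible in the reported event counts but do not erase predictions already
given — mirroring the task, which is to predict each upcoming gesture when
it begins.

## The synthetic generator

The original recordings are not public, so the generator emulates the
acquisition protocol with known ground truth: 8 channels at 1000 Hz, four
base gestures, two-gesture actions of about 5 s (about 2.5 s per gesture),
four-gesture actions of about 10 s, 100 repetitions split 80/20 for
training and validation, ten resplits.

Signal model. Per channel, an amplitude envelope modulates a unit-RMS
in-band carrier (an 80 Hz sinusoid with random phase; any carrier with the
right RMS works because the pipeline consumes only RMS) plus additive
white Gaussian noise. 80 Hz sits inside the 20–150 Hz analysis band and
completes exactly 8 cycles per 100 ms window, so a noiseless steady-phase
window's RMS equals the envelope exactly — a property the tests exploit.

Key generator decisions, fixed once and kept:

* Activation profiles: electrodes ring the forearm and each gesture
  dominates its own sector of the ring (a smooth circular bump over a 0.2
  baseline, ±15% per-channel variation, peaks evenly spaced across the
  four gestures). Independently uniform per-channel amplitudes were
  rejected as unrealistic: all-positive i.i.d. draws are nearly collinear
  (cosine similarity ≈ 0.93), which would make the four gestures
  near-scaled copies of one another — no four distinct hand gestures look
  like that on a forearm armband.
* Transitions: rise and decline are 300 ms linear ramps (≥ 5 feature
  frames at the 50 ms hop). The action's opening rise starts from a rest
  level of 5% of activation, and the closing decline returns to it, but
  *interior* hand-offs are continuous: the front gesture releases to 50%
  of its activation and the rear gesture's own pattern takes over from 50%
  of its activation. Continuous actions do not pass through rest, and this
  matters statistically: with a patternless near-rest valley between
  gestures, the maximum-likelihood state fit clusters frames by amplitude,
  the key state's density engulfs the valley, and the trigger fires on
  declines with no rear-gesture evidence at all. With partial-engagement
  hand-offs the two transition phases overlap in amplitude and EM must
  separate them by channel pattern, which is exactly the evidence a
  prediction should rest on.
* Timing jitter: each gesture segment's duration is jittered ±8%
  uniformly (the protocol's repetitions lasted *about* 5 s). Without it,
  every synthetic trial's transition falls on the same frame, and any
  window setting whose boundary happens to coincide with that frame is
  hit by a pathological alignment on every trial — an artifact cue-paced
  human repetitions cannot produce.
* Subject variation: one multiplicative per-channel factor per synthetic
  subject, drawn from ±15%, applied to all gestures (models are
  subject-specific in the original protocol; the factor emulates electrode
  placement and physiology differences without modeling them).
* Noise: additive noise SD of 0.05 against activations of roughly
  0.2–1.0 arbitrary units. Amplitude units are arbitrary by design; the
  protocol publishes no amplitude statistics.

What the generator does *not* emulate: motor-unit action potentials,
spectral shape, fatigue, electrode shift, co-contraction dynamics, or
label noise in segment boundaries. Passing tests on this generator shows
the pipeline is correct and that the method behaves as described under
its own assumptions; it does not certify accuracy on real recordings.

## Preprocessing

The band-pass is a 4th-order Butterworth (20–150 Hz) and the notch a
narrow biquad at 50 Hz (quality factor 30), both applied
forward-backward, i.e. zero-phase, so ground-truth alignment survives
filtering. The energy-based active segmenter is a reconstruction (the
original is cited but not specified): short-time energy summed over
channels in a 100 ms moving window, baseline statistics from the leading
300 ms, threshold `mean + 3 SD`, minimum supra-threshold run 200 ms. On
synthetic data it locates onsets within one hop of ground truth. The main
synthetic experiments extract RMS over the exact action extent (trials
span the action by construction); the segmenter is exercised by its own
tests and available for recordings with rest padding.

## Training

Baum–Welch with the left-to-right mask; the initial distribution stays
pinned; masked transitions stay exactly zero; a variance floor (1e-6 of
the overall per-channel variance) prevents collapse on near-constant
steady phases. Emissions are initialized from contiguous blocks of each
sequence sized by the expected phase durations — 12% rise, 76% steady,
12% decline per gesture half. Equal-duration blocks (the obvious
alternative) were rejected after they repeatedly converged to a local
optimum whose key-state density sat in the wrong region of feature space;
the phase-proportioned split encodes only what the state semantics already
assert, that transitions are much shorter than stabilization. EM stops at
a relative log-likelihood improvement below 1e-6 or 100 iterations; the
fit is deterministic, and the likelihood trace is checked for monotonicity
in the tests.

`build_bank()` trains each of the twelve models on an 80/20 split,
repeated ten times with reseeded splits; one shared partition per repeat
makes repeat-level validation accuracy (classification of held-out
sequences by total likelihood) well defined, and each action retains its
best repeat by validation log-likelihood.

## Problem sizes and determinism

The study-scale synthetic experiments — also what `scripts/acceptance.R`
runs — use 12 action pairs × 20 repetitions × 2 synthetic subjects for
training/held-out evaluation and 4 four-gesture action types × 15
repetitions for the pruning experiments; the unit tests use a smaller
12 × 6 × 2 fixture. These sizes give 96 held-out two-gesture trials and
180 scored transitions, enough that the reported percentages move in
steps of about 1 point and below. Every stochastic step (profiles,
recordings, subject factors, splits) is seeded, and the whole pipeline is
reproducible bit for bit from one seed.

## Known limitations

* The no-pruning ablation has a structural floor under per-transition
  scoring: the first of three transitions is decoded identically with and
  without pruning, so a working implementation cannot score below one
  third. The ablation lands exactly there (the pruned arm sits far above
  it), which is the meaningful contrast.
* Trigger latency is signal-time, not wall-clock processing time; the
  package makes no claims about computational latency.
* Models are subject-specific, as in the original protocol; there is no
  cross-subject transfer.
* The synthetic generator's realism limits are listed above; in
  particular, real inter-gesture transitions are richer than a
  partial-engagement linear hand-off, and real rest is not white noise.
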