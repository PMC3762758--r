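---
title: "Hybrid BCI decoding: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid BCI decoding: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridBCI)
```

This vignette is the package's own account of the science it implements:
the three decoding protocols, the arbitration and confirmation logic that
hybridize them, the surrogate simulator, and — importantly — what the
synthetic-data generator does and does not emulate, so that the meaning of
a passing test suite is clear.

## The decoding problem

A user wearing a 14-channel consumer EEG headset (10–20 subset AF3, AF4,
F3, F4, F7, F8, FC5, FC6, P7, P8, T7, T8, O1, O2; 128 Hz) remotely steers
a humanoid surrogate through a maze and tells it which of the objects it
encounters is of interest. Three two-class protocols divide the work:
motor imagery toggles the robot's state (walk/stop, or trigger body
alignment), steady-state visual responses to 12/15 Hz flicker turn the
head left/right in 3° steps, and P300 responses to 250 ms object flashes
mark the favorite object. Every protocol is deliberately simple — the
design premise is that a *hybrid of simple protocols* can carry a complex
task on low-cost hardware.

## Motor imagery: CSP + linear max-margin classifier

Trials are band-passed to 8–30 Hz (mu/beta). With the zero-mean assumption
satisfied by filtering, each trial's spatial covariance is estimated as
`X Xᵀ / T` and *trace-normalized* (divided by its trace) before averaging
within class — the standard guard against inter-trial amplitude drift.
Common Spatial Patterns solve

    Σ_active w = λ (Σ_active + Σ_idle) w

by symmetric whitening of the composite covariance followed by an
eigendecomposition; the `m = 2` eigenvectors from each end of the spectrum
become spatial filters. Features are normalized log-variances of the
filtered window, so they satisfy `Σ exp(fᵢ) = 1` and are invariant to
global scaling. A linear-kernel max-margin classifier (cost 1,
config-exposed) separates imagery from idle; its raw decision value is
kept as a confidence for the arbitration log, not only the label.

Numerical choices: eigenvector signs are fixed by making the
largest-magnitude component positive (reproducibility across BLAS
backends); a rank-deficient class covariance receives trace-scaled
shrinkage (`1e-6`) with a warning; near-identical class covariances
(all whitened eigenvalues within 0.05 of ½) are flagged as
non-discriminative.

One subtlety worth recording: with trace normalization, a class that
*carries* a strong rhythm has its noise directions scaled down relative to
the other class, so the discriminative filter for an idle-dominant rhythm
is the one at the *minimum*-eigenvalue extreme. The pattern-recovery tests
read the filter from that end.

## SSVEP: canonical correlation against sinusoidal references

The occipital pair O1/O2 is band-passed 4–50 Hz (artifact reduction, 5th
order Butterworth — the one filter order stated for the system; the same
family is used for every band). For each stimulus frequency the reference
block is `{sin 2πft, cos 2πft}` (one harmonic; a config switch adds the
second), spanning all phases, so the first canonical correlation ρ is
phase-invariant and invariant to invertible mixing of the two channels.
CCA is computed from the two-block formulation `Sxx^{-1/2} Sxy Syy^{-1/2}`
via SVD, with a trace-scaled ridge of `1e-9` on the autocovariances for
numerical safety. The reference duration equals the analysis window (2 s
at 128 Hz).

## P300: xDAWN + Bayesian linear discriminant

Epochs are the 600 ms following each flash onset. At 128 Hz this is 76.8
samples; the epoch length is fixed at `floor(0.6 × 128) = 76` samples (19
after 4× decimation to 32 Hz) — deterministic shapes, and the final
partial sample carries negligible information. Epochs overlap (250 ms
inter-stimulus interval < 600 ms span) and are scored independently on the
shared stream.

xDAWN is fit from the labeled epochs themselves: for onset-aligned
extracted epochs the least-squares evoked-response estimate reduces to the
target-epoch mean, whose outer product is the signal covariance; the total
covariance is the mean epoch outer product. The generalized eigenproblem
(evoked power over total power) is again solved by symmetric whitening,
retaining the top three filters.

The classifier is Bayesian linear regression onto targets ±1 with a bias
column: posterior mean `m = β (β ΦᵀΦ + α I)⁻¹ Φᵀ t`, hyperparameters α
(prior precision) and β (noise precision) iterated through their
closed-form evidence-maximization updates until the relative change falls
below `1e-6` (at most 200 iterations; non-convergence returns the best
iterate with a warning — it occurs on very small training sets, e.g. 20
epochs against 58 feature dimensions). With fixed hyperparameters the
solution is exactly ridge regression with penalty α/β, which the tests use
as a closed-form oracle. All weights including the bias share the prior;
with the modest feature dimension here the distinction from an
unregularized bias is immaterial.

Per-object decisions average the epoch scores over that object's flashes
and compare against a threshold: 0 by default, or the midpoint of the
training class score means (`calibrateThreshold`) — whether the online
system calibrated per subject is not something we assert, so both are
supported. Mean-score aggregation is also what produces the observed
improvement of recognition accuracy with flash count.

## Arbitration and the fading rule

During navigation both protocols run on every 2 s window (250 ms hop).
The pair `(ρ₁₂, ρ₁₅)` is computed for each window; a degree-2
polynomial-kernel max-margin boundary separates the motor-imagery region E
(low correlations — the training cloud contains imagery *and* idle
windows, since both are motor-protocol outcomes) from the stimulus region
S, and a linear boundary splits S into left and right. Both boundaries are
stored as plain kernel expansions, so prediction and JSON serialization
need no fitting library. The frequency→direction mapping (12 Hz = left) is
a config default; nothing in the protocol fixes it.

Confirmed commands come from the dynamic fading feedback rule, a counter
over the classification stream: the first classification becomes the
candidate at level 0; an identical classification increments the level, a
differing one decrements it; once the level has reached zero a further
differing classification drops the candidate (the *next* input is adopted
fresh); reaching level 4 confirms the command and resets the state. Two
design details the rule's prose leaves open were resolved as follows:

- The level-0 semantics above make the reference hand-trace exact: from
  `L, L, R, R, R, R, R, R, R` the confirmation of R lands on the ninth
  input, and the minimum latency from first classification to confirmation
  is exactly five inputs = 1 s at the 250 ms cadence (the test suite
  verifies by exhaustion that no four-input sequence confirms).
- `NONE` (idle) decrements like any differing input but is never adopted
  and never confirmed: idle activity alone can therefore never actuate the
  robot, which is the rule's false-positive-guard intent.

The state resets after each confirmation and on mode transitions. The rule
is applied to the SSVEP/ERD hybrid only, not to P300 decisions.

## The surrogate simulator

The robot state is a point pose (x, y, body heading) with a head offset,
in a 150 × 300 cm walled arena. Positive head offset is leftward
(counter-clockwise from above); head logic is in degrees to match the
3°/9° protocol constants. Walking advances at 3.3 cm/s, body turns at 0.13
rad/s. The command semantics are postural: a head-turn command moves the
head 3°; the imagery switch triggers body alignment when head and body
differ by more than 9° (commands ignored until aligned, after which the
body heading has gained exactly the prior head offset) and otherwise
*toggles* walking — "toggle" being the minimal interpretation of a state
switch that also allows stopping; a start-only semantics would leave no
way to halt. Walking continues until the next switch rather than in fixed
steps. Collisions stop the robot at the wall and drop it to idle.

The vision stage is deliberately a toy: objects render as colored disks
(one hue-like channel) through a pinhole model, the color filter groups
in-range pixels into connected components and reports normalized bounding
boxes, and recognition triggers when the unweighted centroid of the boxes
falls in the half-open central zone `[0.4, 0.6) × [0.4, 0.6)` (the middle
of five zones per axis). It exercises the zone/centering logic, which is
the algorithmic content; photorealism is a non-goal. Recognition mode runs
4 s rest → flash phase of `(n_objects · flashes − 1) × 0.25 + 0.6` s
(2.85 s for two objects, 5.35 s for four, at five flashes) → 2 s result
display, robot stationary throughout.

Navigation metrics need two conventions the protocol leaves to the robot
platform: a forward "step" is one 3.3 cm stride (one second of walking)
and a turning "step" one 0.13 rad increment; transitions count switches
between exploration (head-turn) and navigation (switch) activity in the
confirmed-command sequence.

## The synthetic EEG generator

Every decoder is tested against data with the statistical structure it
assumes, generated reproducibly (identical seed ⇒ bit-identical output):

- **Background**: independent per-channel `1/f^α` noise, α = 1 (pink) by
  default — the simplest EEG-like spectrum — zero mean, unit variance.
- **Motor imagery**: an additive 10 Hz (mu-band) oscillation with random
  phase on FC5, FC6, F3, F4, amplitude `snr` relative to the unit-variance
  background; imagery *attenuates* its amplitude by a fraction (default
  0.7). Amplitude attenuation of a non-phase-locked oscillation is exactly
  the event-related-desynchronization concept.
- **SSVEP**: a random-phase sinusoid at 12 or 15 Hz on O1/O2 at amplitude
  `snr`; optional weak second harmonic.
- **P300**: a randomized equal-count flash schedule at 250 ms spacing;
  favorite-object flashes add a positive half-cosine bump (width 0.2 s,
  peak 0.30 s post-onset, optional latency jitter) through a unit-norm
  parietal-dominant (P7/P8) spatial pattern. Exactly one favorite per
  stream by default; zero or several are permitted, since the per-object
  decision is binary.

Defaults mirror the training-session structure (20 trials per condition,
2 s windows with 250 ms increments, five flashes per object online). No
reported amplitude or SNR figures exist for the recorded subjects, so the
generator's SNR scale is its own; the property tests state the SNR they
run at. What the generator does *not* emulate: volume conduction between
channels (background channels are independent), alpha rhythms and ocular
or muscular artifacts, electrode impedance and placement variability, and
any head-model forward mapping. Passing tests therefore demonstrate
correctness of the algorithms under their assumed signal structure and
well-behaved recovery at stated SNRs — not expected performance on
recorded EEG, which the reported per-subject accuracies (mid-80s % for
the navigation protocols, ~90% recognition, 73% arbiter) describe and
which no synthetic calibration can stand in for.

## Filtering and I/O conventions

Offline/training paths use zero-phase (forward–backward) Butterworth
filtering; whether the original online system filtered causally is
unknown, so a causal flag is provided and the closed-loop simulator simply
applies the same zero-phase filter per sliding window, accepting edge
effects, so that both paths share code. Because plain forward–backward
filtering has severe transients on short segments, all filtering uses
odd-reflection padding at both ends (the scipy convention). Sample indices
are 0-based; window intervals are half-open `[start, start + width)`.

Recordings round-trip through delimited text (header row of channel names
plus a `time_s` column, events in a two-column sidecar) or through a
minimal 16-bit EDF implementation written for this package (one-second
data records; the base EDF layout carries no annotations, so events use
the same sidecar). EDF round trips are exact to the 16-bit quantization of
each channel's range. Fitted models serialize to a JSON container tagged
with their class.

## Problem sizes and determinism in the test suite

The suite fits decoders on 20-trial-per-class sessions, checks oracle
equivalence (CSP and xDAWN against brute-force generalized eigensolvers,
BLDA against closed-form ridge, CCA against the QR-based reference
implementation) on small random instances, measures cross-validated
accuracies and their monotonicity over 3-point SNR grids with 20–40
evaluation runs per cell, and drives one full closed-loop maze run (two
waypoints, ~550 decision steps). These sizes were chosen as the smallest
that make the statistical assertions stable under their fixed seeds; all
randomness is seeded, so the suite is deterministic.

## Known limitations

- The arbiter is fit and exercised on synthetic correlation clouds; the
  overlap structure of real imagery and flicker responses near the mu band
  (the reported arbiter accuracy is far below the single-protocol ones)
  is not reproduced by the generator.
- The surrogate is kinematic: no gait dynamics, no actuation noise, no
  camera noise; collision handling is a point-robot stop.
- Multi-class CSP, adaptive/online updates, filter-bank CCA and speller
  paradigms are out of scope.
- The EDF implementation covers the subset needed for round-tripping this
  package's recordings (equal rates per signal, no annotations).
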