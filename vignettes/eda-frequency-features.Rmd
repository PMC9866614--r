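---
title: "Frequency-spectrum features for wrist-EDA stress detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-spectrum features for wrist-EDA stress detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edafreq)
```

## The problem and the signal

Electrodermal activity (EDA) tracks sweat-gland activation driven by the
sympathetic nervous system. Measured as skin conductance (microsiemens),
it decomposes conceptually into a slow tonic level and short phasic
skin-conductance responses (SCRs) evoked by stimuli. Psychological
stress raises the SCR rate and amplitude, which reshapes the *spectrum*
of short signal windows: stressed segments concentrate energy at low
frequencies, while calmer states leave relatively more broadband
content. `edafreq` turns that observation into a small, cheap feature
set for classifying baseline / stress / amusement states from 4 Hz
wrist EDA, with explicit accounting of detection latency.

The pipeline assumes: a fixed sampling rate; per-sample state labels; no
missing samples (no gap handling or artifact rejection is attempted);
and that a segment short enough to be useful for fast detection (12 s by
default) still carries class-discriminative spectral shape.

## Segmentation

A window of `t_length` samples slides in steps of
`t_step = t_length − t_overlap` over the whole recording, starting at
sample 0. A window becomes a segment only if all its labels agree and
none is `other`; windows that span a state transition are rejected. We
deliberately anchor the window grid to the start of the signal rather
than to each label run — the simplest deterministic rule — and let the
purity test handle run boundaries. Defaults are `t_length = 48` samples
and `t_overlap = 20` (12 s and 5 s at 4 Hz).

Raw conductance sits on a tonic offset of several microsiemens. Without
correction, the DC bin dominates every energy-based quantity, so the
default preprocessing subtracts each segment's own mean, which zeroes
the DC bin exactly. This is configurable (`preprocess = "none"`) for
sensitivity analyses, and spectral energy normalization
(`normalize_spectrum()`) is exposed separately: the band features are
scale-covariant, so normalization changes nothing a scale-insensitive
classifier would see, and the default leaves spectra raw.

## Spectral features

Each segment is transformed with the plain unnormalized DFT (no
windowing function, no Welch averaging — one transform per segment), and
the one-sided magnitudes over bins `0..N/2` are kept; bin `b` sits at
`b·fs/N` Hz, so the default geometry has a 1/12 Hz resolution grid with
the Nyquist bin at 2 Hz.

Per frequency band, three features summarize the in-band magnitudes:
mean, sample standard deviation (divisor `N_b − 1`), and maximum. The
in-band bin count `N_b` is obtained by *counting* bins on the grid, not
from a closed-form product of bandwidth and sampling rate, which is not
consistent with the bin spacing (a 1 Hz band at `N = 48`, `fs = 4` holds
12 bins). Band edges follow a half-open rule `[f_low, f_high)` by
default so that contiguous bands partition the axis and a shared edge
bin is counted exactly once; a closed-interval rule is available via
`edge_rule = "closed"` for fidelity experiments, at the cost of
double-counting shared edges.

The fourth feature, the half-energy frequency, is computed from the full
spectrum: with `psi = |X|²` and its normalized cumulative sum, it is the
smallest bin frequency whose cumulative energy reaches 0.5. We resolve
it on the discrete bin grid without interpolation — interpolating would
invent precision the 1/12 Hz grid does not have — and compare against
0.5 with a 1e-12 absolute guard so that an exactly-half cumulative sum
(e.g. two equal-energy tones) lands on the lower bin regardless of
floating-point rounding direction. The DC bin is excluded from the
energy profile by default (`include_dc = FALSE`); with mean removal the
choice is immaterial. A segment with zero spectral energy (a constant
window after mean removal) raises a typed `zero-energy` condition rather
than returning NaN features; the table builder drops such segments with
a warning.

With `m` bands this yields `3m + 1` base features (7 for the default
0–1 / 1–2 Hz pair).

## Sequence features

Per-segment features fluctuate; their *stability* over consecutive
segments is itself informative (stressed stretches are more homogeneous
in feature space). For each base feature we therefore append its mean
and variance over the `w` most recent segments. Two numerical choices
are worth stating plainly:

* The window covers exactly the `w` most recent segments with divisor
  `w`. (Writing the window as a sum from `k − w` to `k` would span
  `w + 1` terms; we use the self-consistent `w`-term form, which also
  matches the detection-latency accounting below.)
* The variance uses the population normalizer `1/w`, unlike the band
  standard deviation's `N_b − 1`; the two statistics follow their
  respective printed conventions and we keep both as-is.

Windows never cross a subject or label boundary (a mixed window would
have no class), and the first `w − 1` segments of each run yield no row
— we drop rather than pad, so every emitted row is computed from fully
observed data. Feature count triples to `3(3m + 1)`.

## Evaluation and detection latency

Leave-one-subject-out (LOSO) cross-validation: for `J` subjects, `J`
models are trained, each tested on the one subject it never saw, and the
per-subject accuracy and F1 are averaged unweighted — subjects, not
rows, are the unit of generalization. Stress is the positive class in
the binary task (baseline and amusement together form "no stress"); the
three-class task reports macro F1, the unweighted mean of one-vs-rest
F1, chosen because the class sizes are imbalanced and no alternative
averaging is canonical here. A class absent from both truth and
prediction contributes 0 with a warning rather than NaN.

The roster — decision tree (depth ≤ 10), 1-NN and 10-NN, random forests
of 10 or 100 trees (depth ≤ 10, balanced class weights), RBF SVM with
balanced class weights, a bagged SVM (10 bootstrap replicates with
majority vote, the smallest standard bagging construction), and AdaBoost
(SAMME) with 10 random-forest estimators — is deliberately untuned:
the features, not classifier tuning, are the object of study. Features
are standardized with training-fold mean/SD for the distance- and
kernel-based learners (kNN, SVMs) and left raw for the scale-invariant
tree ensembles; the held-out subject never influences the scaling. All
stochastic components fan out deterministically from one seed, so a
report is byte-reproducible.

One decision consumes `w` segments spanning
`TTD = t_length + (w − 1)·t_step` seconds — for the default geometry and
`w = 7`, 54 s. Two experiment drivers explore the trade-off:
`fixed_ttd_grid()` holds TTD constant and sweeps the segmentation
geometry, keeping only cells where the implied `w` is a positive integer;
`window_sweep()` fixes the geometry and sweeps `w`, pairing each score
with its TTD.

## The synthetic cohort generator

`simulate_cohort()` exists so that every stage — segmentation purity,
feature directions, LOSO wiring — is testable end-to-end with no data
download. Each subject is the standard minimal electrodermal model:

* a tonic level drawn uniformly from 2–20 µS per subject, with a slow
  Gaussian random-walk drift (SD 0.003 µS/sample);
* SCRs as a Poisson process per state — 2, 4, and 8 events/min for
  baseline, amusement, and stress — each event a bi-exponential pulse
  `e^(−t/τ_d) − e^(−t/τ_r)` (τ_r = 0.75 s, τ_d = 3 s) scaled to a
  log-normal amplitude (medians 0.3 / 0.4 / 0.6 µS);
* broadband Gaussian noise, largest for baseline (0.08 µS) and smallest
  for stress (0.02 µS);
* a session plan of baseline 600 s, amusement 300 s, stress 600 s,
  labelled exactly.

The class contrasts are designed in, with known sign, so feature-level
regression tests have a predictable direction: stress's frequent large
SCRs concentrate low-frequency energy (higher 0–1 Hz band mean, lower
half-energy frequency than baseline); amusement's SCR rate is redrawn
every 60 s from a log-normal (sdlog 0.7) and its amplitudes are the most
dispersed (sdlog 0.9 vs 0.15 for stress), so amusement features vary
between consecutive segments while stress features — homogeneous
amplitudes, stationary rate, low noise — are stable, giving stress the
lower windowed variance. Signals are clipped below at 0.05 µS so
conductance stays physical.

What the generator does *not* emulate: motion artifacts and sensor
dropout, subject demographics, nonstationarity within the stress state,
tonic/phasic interactions beyond superposition, or the absolute
difficulty of real wrist recordings. Near-perfect synthetic accuracies
therefore validate wiring and effect directions, not expected
performance on real datasets, which is substantially lower.

At the default configuration a 6-subject cohort yields roughly 190
decision rows per subject; the test suite runs its end-to-end checks on
6-subject cohorts and its direction checks across ten generator seeds,
sizes chosen to keep the full suite in the tens of seconds on a laptop
while leaving Poisson-level fluctuations visible.

## Data interfaces

The WESAD adapter reads the dataset's per-subject pickle records through
the `python` interpreter on `PATH` and maps the protocol codes 1/2/3 to
baseline/stress/amusement; every other code (transients, meditation,
auxiliary) becomes `other` and is excluded. The 700 Hz label channel is
aligned to the 4 Hz EDA channel by reducing each block of 175 labels to
its unanimous value, or to `other` when the block is mixed — a
conservative rule that guarantees resampling can never manufacture a
pure-looking label at a state transition. The adapter is optional:
everything else consumes `labeled_signal` objects, constructed directly
or read from plain CSV.

## Known limitations

* No artifact handling: real wrist EDA contains motion spikes and
  dropouts the pipeline will happily segment.
* The purity rule discards all transition windows, so states shorter
  than `t_length` contribute no data at all.
* At 4 Hz the 1–2 Hz band sits against the Nyquist limit; with other
  sampling rates the default bands should be reconsidered.
* LOSO with a handful of subjects has high variance across subjects;
  averaged scores on small cohorts should be read with their per-subject
  spread (`summary()` prints it).
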