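---
title: "Decoding the locus of auditory attention: models, preprocessing and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding the locus of auditory attention: models, preprocessing and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
two decoding models, the preprocessing and validation protocol, the MESD
metric, the synthetic-data generator that stands in for recorded EEG, and
the numerical and design decisions taken where more than one reasonable
choice existed.

## The decoding problem

A listener attends to one of two concurrent speech streams, one per ear.
Two sources of information about attention are believed to be present in
scalp EEG:

* an *envelope-following response*: cortical activity tracks the slow
  amplitude modulations of the attended speech more strongly than the
  unattended speech;
* *spatial patterns* of oscillatory power, notably in the alpha and beta
  bands, that differ with the attended direction.

The linear backward decoder uses only the first source: it reconstructs the
attended envelope from lagged EEG and classifies by Pearson correlation
against the two candidate envelopes, so it needs access to the stimuli. The
CNN uses whatever spatio-temporal structure separates left- from
right-attended windows — in practice largely the second source — and needs
no stimulus information at decision time. This difference is why the CNN
can classify far shorter windows: correlation estimates are noisy over
fractions of a second, but a spatial power pattern is present in every
window.

## Architecture and training

The network maps a 64 × T window (T samples at 128 Hz) to two class
scores: a convolution with five independent 64 × 17 kernels (130 ms at
128 Hz) producing five 1 × T series (zero-padded "same" convolution), ReLU,
average pooling over time to five scalars, a 5 → 5 fully connected layer
with sigmoid, and a 5 → 2 linear layer with softmax cross-entropy — 5487
parameters in total.

Training follows a fixed protocol: mini-batch SGD, batch 20, momentum 0.9,
weight decay 5e-4 applied to all weights and biases, learning rate 0.09
stepped to 0.045 after epoch 10 and 0.0225 after epoch 35, 100 epochs,
weights and biases initialized from Normal(0, 0.5²). After training, the
model from the epoch with the lowest validation loss is kept (first
minimizer on ties). Batches are reshuffled every epoch under the run's
seed, so a (seed, data) pair reproduces training exactly.

Two points were genuinely open and are fixed as follows:

* **Padding.** The convolution output is described as 1 × T per filter,
  which implies zero-padded "same" convolution; `"valid"` is also
  implemented (it yields a length T − 16 series and requires T ≥ 17)
  because unpadded convolution is the default in some toolboxes. The
  package default is `"same"`.
* **Epoch selection metric.** Validation *loss*, not accuracy, selects the
  epoch; the first minimizing epoch wins ties.

## Preprocessing

EEG is bandpass filtered at the native rate (8196 Hz), group-delay
compensated, and downsampled — to 128 Hz for the CNN (1–32 Hz band) and
20 Hz for the linear model (1–9 Hz band). Constraints for the 1–32 Hz
design: passband deviation at most 0.5 dB, stopband attenuation at least
20 dB over 0–1 Hz and 15 dB over 32–64 Hz. The 1–9 Hz filter reuses the
0–1 Hz constraint and applies 15 dB from 1.5 × the upper passband edge
(13.5 Hz) upward, keeping analogous transition proportions, since printed
constraints exist only for the wider band.

Numerical choices in this chain:

* **Equiripple design by reweighted least squares.** The transition bands
  are about 1 Hz wide at a 8196 Hz rate, which forces filter lengths near
  10⁴ taps. Classic Remez-exchange implementations fail to converge on
  these band layouts, so the package computes the Chebyshev (equiripple)
  solution by Lawson-style iteratively reweighted least squares on a
  uniform frequency grid: each weighted least-squares subproblem is solved
  by conjugate gradients whose matrix-vector products are two DCT-I
  transforms (FFTs), and weights are boosted where the ripple bound is
  violated. Transition ("don't care") bands are loosely bounded
  (|A| ≤ 1.15) so the response cannot grow spurious peaks between bands.
  Every design is re-verified on an independent dense grid (≥ 8192 points
  per band, ≥ 20 points per ripple lobe); the design routine is never
  trusted. The filter length is found by escalating from an analytic
  (Kaiser-type) estimate and bisecting to about 5% resolution, so
  "minimal odd order" is minimal relative to this routine and search
  resolution.
* **Transitions carved from the passband.** The printed stopband ranges
  (0–1 Hz, 32–64 Hz) are kept intact and verified over their full extent;
  the 1 Hz-wide transition bands lie just inside the passband (the
  equiripple passband is 2–31 Hz). The alternative — transitions inside
  the stopbands — would make the printed stopband attenuations false near
  their edges.
* **Fourier resampling.** After filtering, signals are band-limited below
  the target Nyquist rate, so resampling is done by spectral truncation,
  which is exact for band-limited signals and handles the awkward
  8196 → 128 ratio (32/2049) without a second long interpolation filter.
  It also subsumes any extra anti-alias stage the 20 Hz path would need.
* **Trimming convention.** Channel power is the 10% trimmed mean of
  squared samples, implemented as 5% per tail (floor of 0.05 n samples per
  tail), the common convention when a total trim fraction is quoted.
* **Normalization.** Per subject, one scalar: the square root of the
  median of the 64 per-channel trimmed powers computed over the training
  portion only; all of the subject's data is divided by it, preserving
  channel proportions. It is applied to continuous trials before
  segmentation — the scalar is the same either way, and continuous-first
  is simpler.
* **Window arithmetic.** T = round(window_seconds × fs); 0.13 s at 128 Hz
  gives T = 17. Windows overlap 50% with hop = floor(T/2) and never cross
  trial or split-segment boundaries.

## Cross-validation

The main scheme is *leave-one-story+speaker-out*: one candidate fold per
story (that story as test set), retaining only folds whose test-story
narrator speaks in no training story. Under the experiment's 4-story,
3-speaker assignment (stories 3 and 4 share a narrator) exactly two folds
survive. Within training stories, the last 15% of each trial is validation
data. EEG trials are assigned to stories by the *attended* story. The CNN
pools training data over all subjects (each subject keeps its own test
set); the linear decoder is strictly subject-specific.

The *every-trial* comparison scheme splits each trial chronologically. The
published fractions (75/15/15) sum to 105%; the package resolves this as
70/15/15, keeping the stated validation and test fractions, and records
the resolution in the split object and run manifests.

*Leave-one-subject-out* trains on N − 1 subjects and tests on the held-out
subject, still under the story+speaker rule.

Normalization statistics are recomputed per fold from that fold's training
assignment; the test suite checks explicitly that changing the fold
changes the subject scale, and that no trial, story or speaker appears on
both sides of a fold.

## The linear baseline

Envelopes of real audio are computed with a 15-band gammatone filterbank
(center frequencies ERB-spaced from 150 Hz to 4 kHz — the audio band of
low-pass-filtered speech stimuli), per-band magnitude compression with
exponent 0.6, and a unit-coefficient sum. The summed envelope is filtered
with the 1–9 Hz specification and resampled to 20 Hz like the EEG; the
bandpass is applied at an intermediate 128 Hz envelope rate, which is
equivalent for the band of interest and avoids designing the 1–9 Hz filter
at the audio rate.

The decoder uses lags 0–250 ms (6 samples at 20 Hz) and plain least
squares on the normal equations; no ridge term by default (one is
exposed). Rank-deficient problems fall back to a pseudo-inverse with a
warning. The decoder is applied to each whole test trial once, and
decision windows correlate the windowed reconstruction with both
envelopes; this keeps 0.25 s windows usable (the kernel width is the lower
bound; 0.13 s windows are excluded). Exact correlation ties and
zero-variance degeneracies classify as "left" and are flagged.

## MESD

The metric models an AAD-driven volume control as a birth–death Markov
chain: K states with relative gains k/(K − 1), one step per decision
(every τ seconds), up with probability p, down otherwise, a failed
down-step at the bottom stays. A design is *stable* when the stationary
distribution puts at least P₀ of its mass at gains ≥ the comfort level c.
After an attention switch the gain starts at the state nearest 1 − c; the
expected switch duration is τ times the expected first-passage time to the
first state with gain ≥ c, computed in closed form and cross-checked
against the first-step linear equations. The MESD minimizes over K (3–50)
and over the supplied operating points; points with p ≤ 0.5 contribute
infinity. No interpolation is done between operating points — only
supplied (τ, p) pairs are evaluated, which is conservative.

The published definition delegates its constants to a separate technical
reference; the package fixes c = 0.6 and P₀ = 0.95 as named constants in
`mesd_config()`, calibrated once against the known anchor — 70% accuracy
at 1 s windows corresponds to an MESD of 5 s — which this implementation
reproduces at 4.88 s (2.4% low). Monotonicity in p, linear scaling in τ,
and the preference for short windows under mildly decaying accuracy curves
are all verified by tests. The metric assumes independent decisions, which
overlapping sub-second windows violate mildly; MESD values at very short
windows should be read as slight underestimates.

## Interpretation analyses

*Band ablation* retests trained (frozen) models on test trials re-filtered
before re-segmentation, either removing one canonical band (δ 1–4, θ 4–8,
α 8–14, β 14–32 Hz) or keeping only that band. Ablation filters are
linear-phase FIR designs (20 dB stopbands, 0.5 Hz transitions) applied
with group-delay compensation, hence zero-phase — windows are not shifted
relative to the segmentation grid.

*Filter topography* averages the squared convolutional weights per channel
over filters and taps, grand-averages over models, and normalizes with the
per-channel power of the training EEG. "Normalized with" is directionally
ambiguous; the package multiplies (the convolution output magnitude is a
product of weight magnitude and input magnitude), and exposes division as
an alternative. The map is invariant to permuting the five filters.

## The synthetic generator

`synth_config()` defaults emulate the full experiment design: 16 subjects,
8 trials × 6 min (48 min per subject), 64 channels at 8196 Hz, four
stories narrated by three speakers with the pairing schedule and
alternating attended ear of the original presentation table, stimuli
shared across subjects. The forward model is additive and linear:

* spatially correlated 1/f background noise (per-subject random mixing of
  independent 1/f sources; exponent 1 by default);
* the attended envelope convolved with a fixed gamma-shaped 0–250 ms
  kernel and projected through a fixed temporal-central topography, scaled
  to `envelope_snr` (default −15 dB — envelope tracking in real EEG is far
  below the noise floor);
* a band-limited oscillatory component (default 14–32 Hz, so the
  band-ablation analysis has a planted beta-band ground truth) whose
  amplitude is twice as large over the attended-side hemisphere as over
  the other (4× power), scaled by `lateralization_gain` (default 0.3 —
  a modest, realistic asymmetry; tests use 2.0 when they need a cleanly
  separable problem and 0 for null controls).

Speech-like envelopes are nonnegative, carry dominant 2–8 Hz syllabic
modulation, have equal RMS across stimuli, and contain pauses whose silent
runs never exceed 0.5 s.

What the generator does *not* emulate: real spectro-temporal structure of
speech (no audio waveforms, only envelopes), eye/muscle/movement
artifacts, electrode drift, inter-subject variability in response latency
or topography, and any nonlinearity of cortical processing. Passing tests
on this data therefore demonstrate that the pipeline recovers planted
structure of the assumed kind without leakage — not that real-EEG accuracy
levels would be reached. The published real-data numbers (median 80.8% at
1 s, MESD medians, etc.) require the original recordings and are outside
what the synthetic data can or should reproduce.

The generator is deterministic: every stochastic element derives its seed
from the master seed plus structural tags (subject, trial, story, part),
so identical configurations produce bit-identical datasets, and stimuli
are reused across subjects exactly as a shared presentation would be.

## Problem sizes used by the test suite

Tests run the full algorithms at reduced scale, chosen once: 2 subjects ×
8 trials of 60 s at a 512 Hz native rate for the main recovery and
ablation checks (40 training epochs), 30–80 s trials for secondary
property checks (25 epochs), and 100 short trials for the generator's
statistical checks. The native-rate (8196 Hz) filter design is exercised
in full, since it is cheap relative to training. The published protocol
values (100 epochs, 10 runs, 7 window lengths, 16 subjects, 6 min trials)
remain the package defaults throughout.

## Known limitations

* The equiripple designs meet all printed constraints but are found by a
  reweighted least-squares route with a finite order-search resolution;
  the returned length can exceed the true minimax-optimal length by a few
  percent.
* The MESD chain constants are calibrated to a single published anchor
  point rather than copied from the metric's defining reference; absolute
  MESD values inherit that calibration (the anchor reproduces within
  2.4%), while comparisons between decoders are unaffected.
* `run_experiment()` holds one preprocessed dataset in memory; very large
  simulated cohorts at the native rate should be written to the container
  and processed per subject.
* The linear pathway's loso scheme is intentionally absent: the baseline
  is subject-specific by protocol.
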