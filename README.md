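# aadecode

Decoding the spatial locus of auditory attention (left vs. right) from
64-channel EEG in a competing two-speaker listening scenario.

In a "cocktail party" situation a listener attends to one of two
simultaneous speakers. Classical auditory attention decoding (AAD)
reconstructs the attended speech envelope from the EEG with a linear
backward model and compares it with the candidate envelopes — accurate, but
only over long decision windows (tens of seconds). This package implements
an alternative that needs no access to the speech at all: a compact
spatio-temporal convolutional network that classifies the *direction* of
attention from short EEG windows, plus everything around it — the
preprocessing chain, the leakage-free cross-validation protocol, the linear
stimulus-reconstruction baseline, the minimal expected switch duration
(MESD) metric, interpretation analyses, and a synthetic-EEG generator so
the entire pipeline runs and is testable without any recorded data.

## The models

**CNN classifier.** A decision window is a 64 × T matrix (T samples at
128 Hz). Five independent 64 × 17 spatio-temporal filters (17 taps =
130 ms) are convolved along time, followed by ReLU, average pooling over
time, a 5 → 5 fully connected layer with sigmoid, and a 5 → 2 output layer
with softmax cross-entropy — 5487 trainable parameters. Training is
mini-batch SGD (batch 20) with momentum 0.9, weight decay 5·10⁻⁴, initial
learning rate 0.09 stepped to 0.045 and 0.0225 after epochs 10 and 35, 100
epochs, Normal(0, 0.5²) initialization; the epoch with minimal validation
loss is kept.

**Linear baseline.** A backward decoder w (64 channels × 6 lags, 0–250 ms
at 20 Hz) is least-squares fitted to reconstruct the attended envelope:
ŝ(t) = Σ_c Σ_τ w(c, τ) x_c(t + τ). Each decision window is classified by
the larger Pearson correlation of ŝ with the two speaker envelopes, which
are computed as gammatone subband envelopes, power-law compressed with
exponent 0.6 and summed with unit coefficients.

**MESD.** Accuracy p at decision window length τ is converted into a single
number — the expected time for a Markov-chain model of a neuro-steered
volume control to complete a stable switch after an attention switch,
minimized over chain designs and over operating points (see the methods
vignette for the chain constants).

**Preprocessing.** Equiripple FIR bandpass (1–32 Hz for the CNN at a
passband ripple of at most 0.5 dB, with stopband attenuations of 20 dB over
0–1 Hz and 15 dB over 32–64 Hz; 1–9 Hz for the linear model), designed at
the native 8196 Hz rate, group-delay compensated, downsampled to
128 Hz/20 Hz; per-subject normalization by the square root of the median of
the 64 per-channel trimmed-mean powers, computed from training data only.

## Worked example

Simulate a small two-subject dataset with a strong planted direction cue,
preprocess it, train the CNN under the leave-one-story+speaker-out scheme
and compute per-subject MESDs:

```r
library(aadecode)

cfg <- synth_config(n_subjects = 2, n_trials_per_subject = 8,
                    trial_duration = 60, fs_native = 512,
                    lateralization_gain = 2, seed = 11)
ds  <- generate_dataset(cfg)
pre <- preprocess_dataset(ds, pathway = "cnn")
res <- run_experiment(pre, model = "cnn", scheme = "story_speaker",
                      windows = 1, n_runs = 1,
                      config = train_config(epochs = 40), seed = 3)
res
#>   subject model        scheme window_seconds fold run  accuracy
#> 1       1   cnn story_speaker              1    1   1 100.00000
#> 2       2   cnn story_speaker              1    1   1  99.57983
#> 3       1   cnn story_speaker              1    2   1 100.00000
#> 4       2   cnn story_speaker              1    2   1 100.00000

mesd(data.frame(tau = 1, p = 0.70))
#> MESD 4.880 s (tau 1 s, p 0.700; 9 states, step 0.125)
```

Each row is the percentage of correctly classified 1 s decision windows for
one subject on one held-out story; with the planted lateralized beta-band
component at gain 2 the problem is cleanly separable and the network
recovers the labels almost perfectly. Setting `lateralization_gain = 0`
removes the cue and accuracy falls to chance. The `mesd()` call shows the
metric's anchor behaviour: 70% accuracy once per second yields a stable
switch in about 5 s.

A thin command-line wrapper over the same functions is installed at
`inst/cli/aad.R` (`simulate`, `preprocess`, `run`, `mesd`, `ablate-bands`).

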