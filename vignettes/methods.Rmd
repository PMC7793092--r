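---
title: "Sleep scoring from actigraphy and heart rate variability: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep scoring from actigraphy and heart rate variability: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Wrist actigraphy infers sleep and wake from movement alone, which makes
it sensitive but unspecific: quiet wakefulness looks like sleep to an
accelerometer. Cardiac autonomic state carries complementary
information — heart rate and heart rate variability (HRV) fall as NREM
sleep deepens and rise again during REM sleep, and the ratio of
low-frequency to high-frequency spectral power (LF/HF) is elevated in
REM. `hypnoscore` implements a scorer that fuses per-epoch activity
counts with 17 HRV metrics computed over a configurable trailing
window, classifies each 30-s epoch as wake, NREM or REM with a
convolutional-LSTM network, and provides the classic UCSD
weighted-window actigraphy algorithm as a movement-only comparator.
Everything downstream of scoring — record-bound detection, sleep
parameters, epoch-by-epoch agreement and Bland–Altman method
comparison — is included, as is a seeded synthetic cohort generator so
the full pipeline can be validated end to end without access-controlled
clinical recordings.

# HRV metrics

For the epoch ending at time $t$ and a window length $L \in \{30, 180,
300\}$ s, the RR intervals whose terminating beats fall in the
half-open window $(t-L,\, t]$ are collected (trailing, i.e. causal,
alignment; a centered variant is available since the windowing of the
scored epoch is a free design choice). Windows clipped at the record
start are computed on the available data and flagged, not dropped.

**Time domain** (9 metrics): MeanRR, SDRR (sample SD), MeanHR (mean of
per-beat $60000/\mathrm{RR}$, the convention of the standard HRV
packages; $60000/\mathrm{MeanRR}$ is available as a switch), Min/Max HR
(extrema of the 5-beat moving average of RR converted to bpm; windows
of fewer than 5 intervals fall back to MeanHR, flagged), RMSSD, pNN50
(successive differences $> 50$ ms divided by the *total* interval
count, the definition used here), the HRV triangular index
(total count over modal bin count of the RR histogram) and TINN (the
baseline width of the best least-squares triangular interpolation of
the same histogram, with the apex pinned at the mode; the left and
right bases are optimized independently, which is exact because the
squared error separates at the apex). Histograms use $1/128$-s bins,
the convention of the HRV software whose output these metrics mirror.

**Frequency domain** (7 metrics): the tachogram is interpolated to an
even 4-Hz grid by cubic spline, linearly detrended, and its PSD
estimated by Welch's method (Hann window; 150-s segments with 50%
overlap when the window holds at least 240 s, a single segment
otherwise). Band powers are trapezoid integrals of the density over
VLF (0–0.04 Hz), LF (0.04–0.15 Hz) and HF (0.15–0.4 Hz), with the
density interpolated at the exact band edges so the three bands tile
the $[0, 0.4]$ Hz axis exactly; peaks are the argmax frequency within
each band. No installed package provides a Welch estimator, so the
package carries its own, validated against analytic sinusoid spectra
(a planted 0.25-Hz, 50-ms modulation is recovered at $0.25 \pm 0.01$ Hz
with power within 15% of the analytic $a^2/2$). VLF fields are flagged
`NA` when the window spans less than 50 s — two periods of the upper
band edge — which means 30-s windows never produce VLF values; see
"Model channels" below for how that interacts with training.

**Stress index**: $\sqrt{\mathrm{AMo} / (2\,\mathrm{Mo}\,
\mathrm{MxDMn})}$ from the 50-ms RR histogram (Baevsky's index, square
root). Bins are centered on multiples of 50 ms so the mode is a round
multiple of 0.05 s; the index is undefined (sentinel) for constant RR.

**Artifact rule**: intervals deviating more than 20% from an 11-beat
running median are counted as artifacts; records with $\ge 5\%$
artifacts are excluded from training and evaluation. This is a simple,
documented detector standing where commercial QRS post-processing
would sit in a clinical pipeline.

# The classifier

The input for epoch $n$ is a $21 \times C$ window: the channel vectors
of epochs $n-10 \ldots n+10$, with record edges padded by replicating
the terminal epoch. Channels are the activity count plus, optionally,
the 17 HRV metrics ($C = 18$). Standardization statistics (per-channel
mean/SD) are computed on training subjects only and reused verbatim at
validation and test time; missing metric values impute to the
(standardized) zero. A channel with no observed values anywhere in
training — e.g. VLF under a 30-s window — standardizes to zero
everywhere, with a warning; a record missing a channel the model was
trained on is an error.

The network is a stack of `n_conv` 1-D convolutions along the 21-epoch
axis (kernel 3, same padding), each followed by batch normalization
and ReLU, then `n_lstm` LSTM layers whose final hidden state feeds a
dense head: sigmoid with binary cross entropy for the sleep/wake task,
softmax for wake/NREM/REM. L2 weight decay is applied to convolution
kernels. The default architecture is 9 convolutional and 4 LSTM
layers; per-layer widths beyond that are free parameters (defaults:
32 filters, 32 LSTM units, L2 $10^{-4}$, Adam at $10^{-3}$), all
exposed in `ha_config()`. Training uses minibatch Adam with class
weights inversely proportional to epoch frequencies, validation loss
evaluated after every epoch, and min-validation-loss checkpointing:
the returned weights are those of the epoch with the lowest validation
loss. Splits are always by subject; train/validation overlap is a hard
error. No deep-learning framework is involved: the forward and reverse
passes are implemented in the package and verified against finite
differences (relative error $< 10^{-4}$ on every layer type), and the
layer parameter counts against closed-form sums.

A random hyperparameter search (`random_search()`) samples pure-CNN
and Conv-LSTM candidates over regularization rate, learning rate,
layer counts and widths, ranks them by validation loss after brief
training, and re-scores the top candidates by subject-level 5-fold
cross-validation. The desk default is 5 + 5 candidates; the
publication-scale 50 + 50 search is a parameter, not a different code
path. CNN-only candidates use global average pooling over the window
axis before the dense head.

The three-class softmax model is the default; collapsing its NREM+REM
outputs yields the binary view, and `n_classes = 2` trains the binary
sigmoid variant directly. Whether the original algorithm was one
three-class model or a binary model plus a REM discriminator is not
decidable from its description; the single three-class head is the
simpler design that produces every reported output.

# The UCSD comparator

The UCSD interpretative algorithm scores each minute from a 7-minute
weighted span — the current minute, the 4 preceding and the 2
following: $D(t) = \sum_{k=-4}^{2} w_k A(t+k)$, sleep iff $D <
\theta$. Thirty-second counts are summed pairwise into minutes (an odd
trailing epoch is carried as a flagged half-minute), the 4 leading and
2 trailing minutes are zero-padded (flagged; this biases edges toward
sleep), and each minute's label is duplicated to its two epochs. The
span is fixed by the algorithm's design; the coefficient values are
configuration, shipped as package defaults in the classic
weighted-window family (`inst/extdata/ucsd_default.yaml`, versioned)
and meant to be overridden with the validated coefficients for a
specific device and count mode. Scoring is monotone: increasing any
count can never flip a wake minute to sleep, a property the tests
exercise under 1,000 random perturbations.

# Record bounds and sleep parameters

When recording start/end are unspecified, SpO2 coverage is the
surrogate: bounds run from the first to the last non-overlapping
5-min (10-epoch) block containing at least 30 s of SpO2 samples.
Within bounds: SPT is the bounded recording time; TST is 0.5 min per
sleep epoch; SE $= 100 \cdot \mathrm{TST}/\mathrm{SPT}$; sleep onset
is the start of the earliest sliding 20-epoch (10-min) span with at
least 10 epochs of sleep (a tumbling-block variant is available since
either reading of "10-min block" is defensible); SOL is the time from
lights-off to that span's start; WASO counts wake from the first sleep
epoch at or after onset — residual wake inside the qualifying span is
latency, not WASO, which keeps the two definitions consistent (an
all-sleep tail after a 50%-sleep onset span yields WASO 0, not half
the span). REM and NREM minutes partition TST. Records with no
qualifying onset span return flagged sentinels for SOL and WASO.

# Evaluation statistics

Epoch-by-epoch agreement uses standard 2×2 definitions for a stated
positive class (sleep vs wake; REM vs NREM+wake; NREM vs REM+wake):
accuracy, sensitivity, specificity, and Cohen's kappa with
marginal-product chance agreement, reported in percent. Kappa is
defined as 0 when either rater is constant. Metrics are computed per
subject and then summarized as mean with a t-distribution 95% CI
(a normal-approximation switch exists); pooled-epoch computation is a
flag, not the default, because subject-level CIs are the meaningful
uncertainty for device comparison.

Bland–Altman comparison uses differences $d_i = \mathrm{ref}_i -
\mathrm{est}_i$, so positive bias means the device *under*estimates
the reference. Reported: bias with t-based 95% CI and paired-t p,
limits of agreement $\mathrm{bias} \pm 1.96\,\mathrm{SD}(d)$, an OLS
trend test of $d$ on the pair means, and MAE. Bias differences
between two scorers are tested by a paired t-test on the
difference-of-differences, since both scorers cover the same
subjects.

# The synthetic cohort

The generator exists to give the classifier and the evaluator inputs
with the statistical structure they assume, at known ground truth.

* **Hypnogram**: first-order Markov chain over W/N1/N2/N3/REM at the
  30-s grid, started in W. The default transition matrix was chosen
  once for realistic overnight structure (persistent N2/N3/REM bouts,
  fragmented wake; stationary composition roughly 27% W, 8% N1, 37%
  N2, 17% N3, 11% REM, i.e. sleep efficiency in the low-70s like
  typical older-adult cohorts). Records default to 960 epochs (8 h)
  and cohorts to 20 subjects, with per-subject seeds derived from the
  master seed.
* **Activity**: stage-conditioned zero-inflated negative binomial —
  wake epochs active with p = 0.95 at mean 1500 counts (overdispersed,
  size 2), sleep stages mostly zero with rare small bursts. With these
  defaults a plain threshold on counts already reaches ≥ 90%
  sleep/wake accuracy, which is asserted as a property: the learning
  task is solvable by construction.
* **RR series**: piecewise-stationary per stage — baseline interval
  $60000/\mathrm{HR}$ plus a 0.1-Hz LF sinusoid, a respiratory-band HF
  sinusoid, and white jitter, each with stage-conditioned amplitude;
  intervals are floored at 250 ms. Defaults encode wake > REM > NREM
  mean HR and an elevated LF/HF in REM. The composition is spectrally
  verifiable: a planted modulation appears downstream at its frequency
  in the corresponding band.
* **SpO2**: per-epoch coverage seconds, full (30 s) except optional
  leading/trailing dropout to exercise bound detection.

What the generator does **not** emulate: real PSG transition
semantics beyond first order, apnea/arousal microstructure, circadian
drift in heart rate, movement artifacts in the ECG, or any
quantitative match to a particular clinical cohort — no public
quantitative stage-conditional distributions back the defaults, which
were chosen for testability. Passing the synthetic validation
therefore shows the pipeline is correct and the model can learn the
planted physiology; it does not certify performance on clinical
recordings.

# Scale of the shipped validation runs

The package's own validation (tests and `scripts/acceptance.R`) runs
the full pipeline at sizes chosen for a single CPU: a 20-subject ×
960-epoch cohort for the main training run with the reduced
`desk_config()` capacity (3 conv × 16 filters, 2 LSTM × 24, ≤ 12
training epochs), and a 12-subject × 480-epoch cohort for the
feature-set comparison, where the REM signal is planted only in the
LF/HF contrast so that a count-only model has no REM information —
the comparison that motivates fusing HRV with movement in the first
place. The full-size architecture and search (9 conv / 4 LSTM, 50+50
candidates) are configuration away, not code away.

# Numerical choices and degenerate inputs

* Histogram bin anchoring: multiples of the bin width (floor) for
  HRVti/TINN; bins centered on multiples of 50 ms for the Baevsky
  mode, so the mode is a round 0.05 s.
* LF/HF is a sentinel when HF power is exactly 0; stress index when
  RR is constant; time-domain metrics when a window has < 2 intervals;
  frequency-domain when < 4 intervals or < 8 s span.
* Ties in modal bins resolve to the first (lowest-RR) bin, in peak
  frequencies to the lower frequency, and in the sliding onset scan to
  the earliest span.
* Determinism: every stochastic step (simulation, initialization,
  batching, splits, search) draws from a seed that is explicit in its
  interface; repeated runs are bit-identical, which the tests assert
  for the generator, training, search, and the CLI.

# Known limitations

* TINN on sparse histograms (very short windows) degenerates toward
  the histogram span; the fallback is documented in `?hrv_time_domain`.
* The Welch estimator's frequency resolution over a 30-s window is
  coarse (single segment); LF/HF from 30-s windows is noisy, which is
  the expected and documented cost of ultra-short HRV.
* The artifact detector is deliberately simple (running-median rule)
  and is not a substitute for visual ECG review.
* Training is single-threaded and CPU-bound by design; the default
  architecture at publication scale is hours, not minutes, of compute.
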