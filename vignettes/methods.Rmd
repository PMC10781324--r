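---
title: "Translating wrist IMU signals to lower-limb sites: models, training and gait analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translating wrist IMU signals to lower-limb sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaittrans)
```

## The problem

Temporal gait analysis — stride, stance and swing durations, step
frequency — is most accurate when the inertial sensor sits on the
tibia or the shoe, where toe-off (TO) and heel-strike (HS) events
produce sharp, well-separated signal features. Those placements are
impractical for daily monitoring; a wrist-worn device (smartwatch,
smart band) is what people actually wear. The wrist signal, however,
is a heavily smoothed, attenuated, phase-lagged relative of the
lower-limb motion: its angular-velocity waveforms are sine-like, good
for counting steps but poor for resolving stride phases.

`gaittrans` learns the map from six wrist channels — acceleration
$(a_x, a_y, a_z)$ in g and angular velocity
$(\omega_x, \omega_y, \omega_z)$ in deg/s, sampled at 50 Hz — to the
six channels a tibia- or shoe-mounted sensor would record, window by
window, and then estimates temporal gait parameters from the
translated signal with a classical gyroscope event detector.

## Windowing and scaling

All models consume and emit fixed windows of 256 samples x 6 channels;
at 50 Hz one window spans 5.12 s, enough for at least two full strides
at ordinary cadence. Windows are cut with a configurable hop
(default 256, i.e. non-overlapping) and trailing samples are dropped.

Each channel is min–max scaled to $[0,1]$ with parameters fitted **on
the training split only** and reused for validation, test and
inference; values outside the fitted range at inference time are
clipped. A degenerate channel (constant in training) maps to 0. These
conventions fix the inference contract and avoid test-set leakage;
per-channel (rather than global) scaling keeps the low-amplitude
acceleration channels from being flattened by the large gyroscope
ranges.

## The four architectures

All four networks share the contract *scaled 256x6 in, 256x6 out*:

* **Dense autoencoder** (`dense_ae`): flatten to 1536, encoder
  512-256-128 (ReLU), decoder 256-512-1536 (sigmoid head), reshape.
  The final width must be 1536 = 256 x 6; a 1024-unit output cannot be
  reshaped to six 256-sample sequences.
* **Convolutional autoencoder** (`cnn_ae`): encoder
  Conv(64,k3)-MaxPool2-Conv(128,k3)-MaxPool2-Conv(256,k3) (all ReLU,
  length-preserving), so the latent sequence is 64x256; decoder
  TranspConv(256,s2)-TranspConv(128,s2)-TranspConv(64,s1) and a
  sigmoid Conv(6,k3) head, restoring 256 samples.
* **CNN-LSTM** (`cnn_lstm`): Conv(64,k3,ReLU) then LSTM(64) and
  LSTM(6), both emitting full sequences so one call translates a whole
  window. The tanh output of the last LSTM spans $(-1,1)$, which
  covers the $(0,1)$ target band without an extra squashing layer.
* **U-Net** (`unet`): the `cnn_ae` contraction plus skip connections
  in the expansion — the upsampled activations are concatenated with
  the matching-length contraction activations (256+128 = 384 channels
  at length 128, 128+64 = 192 at length 256) before the next
  transposed convolution.

Design choices where the layer tables alone underdetermine the
network: convolutions use symmetric zero padding (length-preserving);
transposed-convolution strides are (2, 2, 1), mirroring the two
pooling steps — the only assignment that restores length 256; pooling
rows carry no activation; transposed convolutions are implemented as
zero-stuffing upsampling followed by a length-preserving convolution,
which has exactly the conv parameter count
$C_{in} k C_{out} + C_{out}$. Weights are initialised uniformly with
fan-in scaling $U(-1,1)/\sqrt{fan_{in}}$ under a caller-supplied seed;
LSTM forget-gate biases start at 1.

The engine behind these layers (dense, conv via im2col, maxpool,
transposed conv, LSTM, Adam) is implemented in R on BLAS matrix
products; every backward pass is verified against central finite
differences in the test suite, and total parameter counts are asserted
against the closed forms (dense $in \cdot out + out$; conv
$in \cdot k \cdot out + out$; LSTM
$4((in + units) \cdot units + units)$).

## Two-stage training protocol

1. **Unsupervised pretraining** (autoencoders and U-Net only): train
   with wrist windows as both input and label, so the encoder learns a
   generic representation of wrist motion from abundant unlabeled
   data.
2. **Freeze** the feature-extraction (contraction) layers.
3. **Translation training**: minimise the MSE between the model output
   on scaled wrist windows and scaled target-site windows with Adam at
   learning rate 1e-3; only the reconstruction layers move.
4. **Fine-tuning**: unfreeze everything and continue at 1e-4.

The CNN-LSTM skips stages 1, 2 and 4 and is trained directly on the
translation pairs. Windows are split 70/15/15
(floor/floor/remainder under a seeded permutation) into
train/validation/test; early stopping watches the validation loss
(patience 10 by default) and restores the best-epoch weights. Epochs
(100), batch size (32) and patience are configuration defaults — the
protocol fixes the loss, the optimiser and the two learning rates but
not these — and every stage is bit-reproducible
under a fixed seed.

## Evaluation

Per-channel MAE and RMSE are computed **in physical units** (g,
deg/s), i.e. after the model output is mapped back with the target
site's scaling parameters; pooling is over every sample of every test
window (not per-window means of means — the difference is
second-order, but the pooled form is the simplest unbiased choice). A
test asserts that scaled-space errors do not reproduce the
physical-unit table whenever the scalers are non-trivial, which guards
against the classic mistake of reporting unit-range errors.

## The synthetic gait simulator

Because the recorded dataset cannot ship with the package, all tests
run on a simulator that reproduces the *structure* of multi-site gait
recordings:

* **Shoe gyroscope y**: per stride, a smooth positive swing lobe
  between toe-off and the next heel strike — a raised-cosine
  ($\sin^2$) shape whose value *and slope* vanish at the phase
  boundaries — plus two sharp negative Gaussian spikes (width about
  40 ms, so a 50 Hz grid resolves them with 2–3 samples) centred at
  the exact TO and HS sample times. The zero-slope lobe edges matter:
  they keep the lobe from biasing the filtered spike peak location, so
  event recovery is exact in the noiseless case.
* **Shoe acceleration**: sharp positive peaks at each heel strike over
  a 1 g gravity baseline plus mild stride-frequency body motion.
* **Tibia**: an attenuated (x0.7), slightly smoothed copy of the shoe
  channels.
* **Wrist**: the shoe channels low-pass filtered (default 3 Hz),
  gain-scaled (x0.4), delayed (80 ms) and mixed with a
  stride-frequency sinusoid — sine-like, as wrist signals are. Because
  the wrist is a *deterministic function* of the shoe signal, a
  sufficiently expressive network can in principle invert it; this is
  what grounds the learnability tests.

Default amplitudes are chosen to be realistic for walking: swing lobe
300 deg/s, TO/HS spikes 250 deg/s (lower-limb gyroscope event peaks
commonly reach 200–300 deg/s), heel-strike acceleration 3 g, stride
period 1.1 s with 0.02 s jitter, stance fraction 0.6. Additive
zero-mean Gaussian noise is parameterised by `noise_sd` in deg/s on
the gyroscope channels; acceleration channels receive it scaled by the
amplitude ratio so both modalities keep the same relative noise.
All randomness flows through a single seeded generator, so identical
seeds give identical sessions.

What the simulator does **not** emulate: biomechanically faithful limb
kinematics, turning, stairs, running, multi-subject variability,
sensor drift or orientation shifts. Passing tests therefore
demonstrate that the pipeline is correct and that the architectures
can learn a smoothing-type wrist-to-shoe map — not that they reach any
particular accuracy on real recordings.

## Gait event detection

The detector follows the classical shoe/tibia gyroscope approach. Both
TO and HS appear as sharp peaks in the (suitably oriented) y-axis
angular velocity; the gyroscope resultant
$\sqrt{\omega_x^2+\omega_y^2+\omega_z^2}$ separates them, because it
stays high for the duration of the swing phase:

1. low-pass filter (zero-phase Butterworth, order 4, cutoff 5 Hz by
   default — 12 Hz is the classical choice for raw signals; the
   narrower default also suppresses reconstruction noise in translated
   signals);
2. optionally invert y (`invert_y = TRUE` for shoe/tibia sites, whose
   swing lobe has the opposite polarity to the event spikes);
3. candidate events = local maxima with prominence at least 20% of
   $\max|\omega_y|$;
4. upward crossings of a threshold (default 50 deg/s) in the resultant
   mark swing onsets — a crossing only counts if the resultant stays
   above the threshold for at least 80% of the following 200 ms,
   which rejects noise blips and the brief heel-strike spike;
5. the candidate peak nearest the upward crossing is the toe-off; the
   peak nearest the *downward* crossing (swing end) is the heel
   strike;
6. any same-label adjacent pair is resolved by dropping the less
   prominent peak, so the output always alternates TO/HS.

Two numerical points discovered during validation are worth recording.
First, zero-phase filtering in `lowpass()` uses odd-reflection padding
before the forward–backward pass; without it the filter start-up
transient corrupts the first ~0.5 s. Second, when noise is
appreciable, the resultant must be computed from the *filtered* axis
signals (and then filtered again): the Euclidean norm rectifies
wide-band noise into a positive DC offset — about 46 deg/s at a
30 deg/s per-axis noise level, i.e. at the detection threshold itself —
which no post-hoc low-pass can remove. `detect_events_series()` does
both.

Temporal parameters follow from the events: stride = successive heel
strikes; **gait (step) duration = half the stride duration**, the
single-foot estimate available from one sensor (the reference values
0.568 = 1.136/2 and 0.554 = 1.108/2 follow this rule exactly); stance
= HS to next TO; swing = TO to next HS; means over all complete
cycles. `compare_gait_parameters()` reports absolute differences in
milliseconds.

## Degenerate inputs and tie-breaks

* Empty or too-short series: `window_signal` returns zero windows;
  `compute_gait_parameters` needs two heel strikes and errors
  otherwise; the detector returns an empty event set (no error) when
  less than one full cycle is present.
* Max-pooling ties go to the earliest sample; gradient routing follows
  the same choice.
* Scaling a constant channel maps it to zero rather than dividing by
  zero; inversion restores the constant.
* The alternation repair in the detector loops until no same-label
  neighbours remain; it terminates because each pass removes one peak.

## Problem sizes used in tests

The shipped tests and the acceptance script run the whole pipeline at
desk scale, chosen so that the full suite completes on a single CPU
core: the learnability task uses one 240-stride noiseless session cut
into 48 window pairs (about 4.4 minutes of walking), 70/15/15 split,
pretraining capped at 10 epochs and translation training at 30 (batch
16, patience 8); the ranking comparison repeats this for three seeds
and three architectures; detector robustness uses 20 noisy 15-stride
sessions. The corresponding study-scale corpora (7200 wrist windows,
1000 translation pairs, 100 epochs) are emulated by the same code
paths — nothing in the implementation depends on the reduced sizes.

## Known limitations

* The engine is CPU-only and trains small models at desk scale; it is
  a faithful implementation of the architectures, not a
  high-performance framework.
* The simulator's wrist-shoe relation is invertible by construction;
  real wrist-to-tibia translation is harder (orientation shifts, arm
  swing decoupling), and per-channel errors on real data will be
  larger than the synthetic figures.
* The detector's threshold (50 deg/s) and prominence fraction (20%)
  are tuned for walking-range amplitudes; running or shuffling gaits
  would need different settings.
* `mean_gait_s` is defined as half the stride duration; if left/right
  step asymmetry matters, a two-sensor setup is required.
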