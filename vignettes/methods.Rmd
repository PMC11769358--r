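---
title: "Scalp-to-intracranial EEG translation: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scalp-to-intracranial EEG translation: model, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Interictal epileptiform discharges (IEDs) — spikes or sharp waves followed by
a damped slow oscillation — are biomarkers of epileptic tissue, but most of
them never reach the scalp: in concurrent scalp / foramen-ovale recordings of
temporal lobe epilepsy only roughly one in five IEDs annotated on the
intracranial traces is visible to a scalp reader. `eegtranslate` learns a map
from a scalp segment $X \in \mathbb{R}^{L\times M}$ to the concurrent
intracranial segment $Y \in \mathbb{R}^{L\times \bar M}$, so that IED
detection can operate on the estimated intracranial signal
$\tilde Y = G(X, z)$ rather than on the scalp directly.

## Model and objectives

The translation model couples a variational encoder with a conditional
adversarial generator:

* **Encoder.** Strided (`stride 2`) temporal convolutions with instance
  normalization and leaky ReLU halve the temporal dimension
  `encoder_layers` times; two dense heads emit the posterior mean $\mu$ and
  log-variance, with $\sigma = \exp(\tfrac12\log\sigma^2)$ guaranteeing
  positivity. The latent sample uses the reparameterization
  $z = \mu + \epsilon \odot \sigma$, $\epsilon \sim N(0, I)$.
* **Generator.** $z$ passes through a dense layer to the coarsest temporal
  resolution $L/2^{I_{up}}$, then through `generator_stages` SPADE-ResNet
  stages. Each SPADE block normalizes its activation *sensor-wise* (per
  channel over batch and time, $\varepsilon = 10^{-5}$) and modulates it
  elementwise with $\gamma$ and $\beta$ maps convolved from the scalp input,
  which is average-pooled along time to the stage's resolution (the pooling
  choice is ours; any antialiasing downsampler would do). A SPADE-ResNet is
  two SPADE → tanh → convolution units plus a skip path; when channel counts
  differ the skip becomes a SPADE-modulated 1×1 convolution. After each stage
  the activation is upsampled ×2 by nearest-neighbour repetition followed by
  a convolution (avoiding transposed-convolution checkerboarding). Two LSTM
  layers over all $L$ steps and a time-distributed dense + tanh head produce
  $\tilde Y$ bounded in $(-1, 1)$.
* **Discriminator.** A Markovian (patch) discriminator with patch size
  $1 \times \bar M$: the same strided temporal convolution stack scores each
  intracranial sensor independently (sensors are folded into the batch), the
  last layer carrying no normalization or activation. All intermediate
  feature maps are exposed for feature matching.

Training alternates per batch: a discriminator step minimizes the hinge loss
$\mathbb{E}[\max(0, 1 - D(Y))] + \mathbb{E}[\max(0, 1 + D(\tilde Y))]$ on
real versus *detached* generated segments, then an encoder+generator step
minimizes

$$L_G = -\mathbb{E}[D(\tilde Y)] + \lambda_1 L_{KL} + \lambda_2 L_{L1}
  + \lambda_3 L_{FM},$$

with a fresh $\epsilon$ per sample per step. Expectation conventions (fixed
and covered by the $\lambda$ scales): the KL term is summed over latent
dimensions and averaged over the batch; $L_{L1}$ is the elementwise mean
absolute difference; $L_{FM}$ sums $\|\cdot\|_1$ over each discriminator
layer scaled by $1/F_i$ ($F_i$ = feature-channel count) and averages over
the layer's leading (batch) dimension. Defaults
$\lambda = (0.05, 100, 10)$ follow the conventions of conditional
image-translation systems — small KL pressure, dominant reconstruction,
moderate feature matching; for reconstruction-oriented experiments a smaller
$\lambda_3$ (e.g. 1) reduces gradient noise from the feature term.

### Optimizer and implementation

No deep-learning framework for R is involved: forward and backward passes
run on a compact tape-based reverse-mode autodiff engine (`R/autodiff.R`),
with the LSTM fused into a single tape node with hand-written
backpropagation-through-time for speed. All gradients are verified against
central finite differences in the test suite. Optimization is Adam with
$(\beta_1, \beta_2) = (0.5, 0.999)$ — the usual choice for hinge-loss GANs —
at step sizes `lr_g = lr_d = 2e-4` by default; CPU-scale experiments in the
tests use larger steps (5e-3 / 2e-3) and two generator updates per
discriminator update (`g_steps = 2`), which roughly doubles reconstruction
progress per epoch at equal wall time. The discriminator step never touches
encoder/generator parameters and vice versa (asserted by parameter
snapshots).

## Classifier and protocols

The IED/non-IED classifier is a compact convolutional network in the EEGNet
style with two deliberate modifications: **no batch normalization** anywhere
and **max pooling** instead of average pooling. Stages: shared temporal
convolution applied per sensor; depthwise spatial combination across sensors
(realized as a dense matrix multiplied by a fixed block mask, which ties
each temporal filter's sensors to its own spatial outputs); max pool;
separable temporal convolution (masked depthwise + pointwise); max pool;
dense sigmoid head. Dropout (0.25) follows each pooling stage during
training.

In both evaluation modes the classifier is trained on *estimated*
intracranial segments (the translation of the training scalp data), matching
deployment where only scalp EEG exists. Intra-subject evaluation uses a
70/10/20 split, stratified by label and seeded (whether the original splits
were stratified is unstated; stratification removes label-imbalance variance
at these segment counts). Inter-subject evaluation maps the held-out
subject's scalp data through every selected training subject's model, scores
each with that subject's classifier, and averages the probabilities; the
ensemble contains exactly the subjects whose intra-subject accuracy strictly
exceeds 0.70. The decision threshold is 0.5 with ties classified IED (the
threshold and tie rule are unstated upstream; both are documented contracts
here).

## The synthetic cohort

Real concurrent scalp/FO recordings are not public, so every downstream
stage is exercised on a simulator that emulates their structure:

* **Intracranial background**: white noise shaped by a leaky-integrator
  (coefficient 0.9) to a 1/f-like spectrum, unit RMS per channel, with a
  weak (0.3) common-mode correlation across channels. Nothing upstream
  specifies the background; this is the minimal realistic choice.
* **IEDs**: a biphasic spike (second derivative of a Gaussian, width ~60 ms,
  peak amplitude 8× the background RMS) followed by a damped sinusoid
  (6–10 Hz, decay constant 60–100 ms, amplitude 0.4 of the spike), placed at
  sample 32 of the 64-sample window on a random subset of 4–8 intracranial
  sensors with lognormal-ish gain spread. Quantitative IED morphology is not
  specified anywhere; these defaults are config-exposed
  (`ied_template()`), not asserted facts.
* **Forward model**: scalp = `attenuation · F(Y · mixingᵀ) + noise`, with
  `F` either the identity or a mild tanh saturation (input gain 0.25 — strong
  saturation would clip spike peaks and decouple scalp visibility from spike
  transmission), Gaussian sensor noise set from the realized signal power to
  hit `snr_db` exactly (the realized SNR is asserted within 0.5 dB), and a
  separate `spike_leakage` gain on the transient component reflecting the
  deeper origin of spike sources.
* **Visibility calibration**: the clinical tables define scalp visibility by
  a neurologist's reading, which cannot be simulated; the stated proxy is a
  fixed peak-threshold detector (per channel: peak |amplitude| in the onset
  window over the MAD outside it, visible if any channel exceeds 6).
  `simulate_cohort()` bisects `spike_leakage` until a 800-segment probe
  subject reproduces the target visible fraction (default 18.8%). The
  detector has a small false-alarm rate on pure background, so the
  "invisible" extreme saturates near, not exactly at, zero.

What passing tests on this cohort do **not** show: robustness to artifacts
(the preprocessing deliberately excludes artifact rejection), to electrode
displacement across sessions, to inter-subject anatomical variability beyond
seed-level variation, or to the far lower SNR of real scalp recordings. The
"easy" cohort used in the recovery tests (identity nonlinearity, 25 dB SNR,
no attenuation, sharp width-0.6 sensitivity profiles) is intentionally close
to linearly invertible — with the default smooth profiles the mixing is so
ill-conditioned that even the optimal linear inverse leaves more than half
of the mean absolute signal unexplained, which would say nothing about the
optimizer.

## Preprocessing

Both streams are high-pass filtered at 1 Hz (4th-order Butterworth) and
notch filtered at 50 Hz (RBJ biquad, Q = 30), both applied forward-backward
for zero phase: filter family and order are unstated upstream, and zero
phase preserves spike morphology. `signal::filtfilt` does not condition the
filter state at the edges, so the package pads by odd reflection and
discards the pads. The common average reference is applied to the scalp
only. Amplitudes are min–max normalized to $[-1, 1]$ **per recording**
(whether normalization was per subject, recording or segment is unstated;
per recording preserves relative amplitudes across segments, which the
visibility detector relies on). Segments are 64 samples, $[{\rm onset}-32,
{\rm onset}+32)$, with the onset at in-window sample 33 (sample 32 in
0-based indexing); matched non-IED segments are drawn seeded from stretches
disjoint from every IED window.

## Storage and interoperability

Cohorts are stored as NPZ archives (NumPy `.npy` members in an uncompressed
ZIP container) written natively — no HDF5 binding ships with the targeted R
installation, and NPZ keeps the files loadable from Python with
`numpy.load`. The reader also inflates deflate-compressed members, so
`numpy.savez_compressed` archives import cleanly. EDF import covers the
common case of continuous clinical exports; channels must share one
sampling rate (resampling is out of scope). Checkpoints store every network
array under slash-separated keys beside the architecture JSON, so any NPZ
reader can inspect them.

## Numerical and test-size choices

Default test and acceptance runs use reduced widths (latent 16, base
filters 4–16, LSTM 32) on 128-segment subjects for 30 epochs — about two
minutes per model on one CPU — which is enough for the easy-cohort
contracts: training L1 falls below half its initialization value, and the
trained model's held-out per-sensor Pearson correlation beats both the
untrained model and the SPADE-free ablation in the majority of three seeds.
The ablation ordering mirrors the reference ablation table directionally;
numeric reproduction of the clinical tables is impossible without the
clinical data (and the original architecture depths were never published —
`arch_config()` therefore exposes every depth/width with documented
defaults: $I_E = 4$, $l_e = 5$, $C_e = 16$ doubling per layer, $I_{up} = 4$,
$l_d = 5$, discriminator depth 4, LSTM width 64, leaky-ReLU slope 0.2).

Known limitations: unidirectional LSTMs bound how fast full-resolution
temporal detail is reconstructed; the per-sensor patch discriminator never
sees cross-sensor structure (a faithful consequence of the $1\times\bar M$
patch design); "normalized Gaussian noise" for the encoder-free ablation is
read as unit-Euclidean-norm scaling (unit variance is the other defensible
reading); and the cohort-level Mean rows of the reference tables cannot
always be reproduced from their own printed per-subject entries — the mean
of the printed visible percentages rounds to 18.9 against a printed 18.8,
and the mapping table's PCORR/COSSIM means show the same last-digit
artifact, so those aggregates are compared against independent
recomputation instead.
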