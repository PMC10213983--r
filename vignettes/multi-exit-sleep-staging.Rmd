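---
title: "Adaptive-depth sleep staging: model, training regimen, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive-depth sleep staging: model, training regimen, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepExit)
```

## The problem and the model

Clinical sleep staging assigns one of five AASM classes (W, N1, N2, N3, REM)
to every 30-second epoch of an overnight polysomnogram. Multimodal networks
that read EEG, EOG and EMG together are more accurate than EEG-only models,
but they spend their full computational budget on every epoch, although a
large share of epochs — a quiet N3 epoch with dominant slow waves, say — is
already unambiguous from the EEG alone. `sleepExit` implements a multi-exit
architecture built around that observation: modality-specific feature
extractors feed three classifier exits of increasing depth, and at inference
an uncertainty gate lets easy epochs leave the network early.

The pieces, in the order a sample meets them:

**Per-modality feature extractor.** Each modality's 30-s waveform passes two
parallel 1-D convolutional branches: a small-kernel branch (kernels 64/8/8,
strides 8/1/1, one 8-wide max-pool) whose first-layer window spans 0.64 s at
100 Hz and resolves fast rhythms (theta, alpha, spindle-band activity), and a
large-kernel branch (512/6/6, strides 64/1/1, 2-wide pool) whose 5.12-s
window captures slow-wave (delta) content. Every conv layer is followed by
batch normalization and a leaky-ReLU. Branch outputs are aligned to a common
length `d_out = 8` by adaptive max-pooling and concatenated channel-wise,
then refined by a convolutional block attention pair: *channel* attention
(global average- and max-pooled channel statistics through a shared
bottleneck MLP, sigmoid-gated, rescaling rows) followed by *spatial*
attention (channel-wise mean/max profiles convolved with one width-7 filter,
rescaling columns). Both gates strictly preserve the C x d shape; attention
weights live in (0, 1).

**Exit heads.** Exit L consumes exactly the first L modalities (EEG; EEG+EOG;
EEG+EOG+EMG). The L x C x d feature stack is recalibrated by a
squeeze-and-excitation gate — two shape-preserving 1x1 convolutions over the
modality axis, a global average pool to one scalar per modality, two more
1x1 convolutions and a sigmoid, applied as the residual `F + gate * F'` — so
the network can weight whole modalities by their usefulness for the current
sample. The stack then flattens to L*C tokens of length d and passes one
transformer encoder block (8-head scaled dot-product self-attention,
residual + layer norm, position-wise feed-forward, closing layer norm), and
finally two linear layers and a softmax over the five stages.

**Two-stage training ("train twice, infer once").** Stage 1 trains the three
feature extractors and the deepest exit with cross-entropy; the early exits
are untouched. Stage 2 freezes everything trained in stage 1 (parameters
*and* batch-norm statistics) and trains the two early exits by
self-distillation: each student minimizes `KL(p_student || p_teacher)`
against the frozen final exit's output distribution. Labels can optionally
be mixed in through a weighted cross-entropy term (`ce_weight`), but the
default regimen is pure distillation.

**Entropy-gated inference.** The uncertainty of an exit's prediction is its
normalized entropy, `sum(p log p) / log(1/N)`, which is 0 for a one-hot
distribution, 1 for the uniform one, and base-invariant. A single threshold
— *Speed* — gates the two student exits: a sample halts as soon as its
uncertainty is strictly below Speed. Speed 0 therefore routes every sample
to the final exit (the gate can never fire, and the early heads are not
evaluated at all); Speed above 1 halts everything at the EEG exit. Routing
is implemented by progressive sub-batching, so the computation that the
trace says was skipped genuinely never ran — `withOpCount()` can verify it.

## What the synthetic generator emulates — and what it does not

No public recordings ship with the package; every test runs on synthetic
epochs from `synthesizeDataset()`. The generator reproduces exactly the
statistical structure the architecture exploits:

- *Stage-specific EEG spectra.* Each stage has a fixed template of relative
  band amplitudes (delta 0.5–4, theta 4–8, alpha 8–13, beta 13–30 Hz);
  waveforms are sums of band-limited sinusoids (frequency uniform within the
  band, random phase, two per band) plus Gaussian noise with `noise_sd = 1`.
  Delta is the strict maximum for N3 and alpha dominates delta in W, so
  slow-wave sleep and wake are spectrally separable the way the two kernel
  scales assume.
- *Modality-specific cues.* EOG carries biphasic eye-movement events at a
  stage-dependent Poisson rate (frequent in W and REM, rare in N3); EMG
  carries stage-dependent muscle tone and burst rate (high tone in W, near
  atonia in REM). Because training z-scores each epoch per channel, the
  discriminative EMG cue is deliberately temporal (burst rate and
  burst-to-baseline contrast), not raw amplitude.
- *Difficulty tiers.* `eeg_separable` epochs keep the full EEG signature.
  `eog_required` epochs blend the EEG template to the midpoint of a
  confusable-pair partner (W with N1, N2 with N3, REM with N1), leaving the
  EOG rate as the disambiguating cue. `emg_required` epochs replace the EEG
  template with the across-stage mean and the EOG rate with the mean rate,
  so only the EMG channel identifies the stage. A depth-one stump on EEG
  delta power separates N3 from W almost perfectly on tier-1 epochs and
  near-chance on tier-3 epochs — the structural gradient the router turns
  into early exits. (An earlier design blended tier-3 EEG within the same
  pairs as tier 2, but W and N3 then remain delta-separable, which defeats
  the tier's purpose; the across-stage mean is the minimal change that makes
  EEG genuinely uninformative.)
- *Class mix.* Default class proportions are the normalized stage counts of
  the 20-subject Sleep-EDF cohort (19.3 / 6.9 / 41.4 / 14.2 / 18.2 percent),
  with largest-remainder apportionment so realized counts are within one
  epoch of quota. Everything is bit-reproducible from the config seed.

The generator is *not* a physiological simulator: no K-complexes, spindles,
artifacts, inter-subject variability, or stage transitions with temporal
context. Passing tests therefore demonstrate that the architecture, the
training regimen and the router behave as designed on data with the assumed
structure — not that any particular accuracy transfers to real recordings.

## Reference configuration and cost accounting

`sleepNetConfig()` fixes the published topology (kernel sizes, strides,
first-layer pooling, attention placement) and documents the free widths:
branch filters `f1 = 84, f2 = 52, f3 = 32` (so C = 64 fused channels),
classifier hidden width 286, one encoder block with H = 8 heads,
feed-forward width 16, CBAM reduction ratio 8, leaky-ReLU slope 0.01,
dropout 0.5 after the first pooled block. The widths were chosen once, with
the package's closed-form counters, so that the reference configuration
reproduces the published cost envelope of the architecture — 10.28 GFLOPs
for a 256-epoch batch routed to the final exit and 1.29 M trainable
parameters with all exits counted — under the documented convention
(1 multiply-accumulate = 2 FLOPs; bias adds not itemized; batch/layer norm,
sigmoid and softmax counted at 4/8/4/5 per element; pooling one comparison
per discarded element). `countFlops()` enumerates exactly the operations the
forward pass executes — the instrumented counter (`withOpCount()`) agrees
with it to the operation — and `countParams()` matches the realized
parameter tree exactly.

Cost attribution under routing follows the semantics of the Speed knob: a
sample's path cost is the feature extractors it traversed plus the head that
emitted it. Gate-only evaluations at earlier heads are not charged, which
keeps the expected cost a convex combination of per-exit path costs, equal
to the full-depth cost at Speed 0 and monotone non-increasing in Speed.
`reducedSleepNetConfig()` (filters 16/16/8, hidden 32) shares the topology
at a fraction of the cost and is the configuration used by the training
tests.

## Numerical and design choices

Choices the source architecture leaves open, and how this implementation
resolves them (all are config-overridable where that is meaningful):

- *Attention score scaling* uses the conventional `1/sqrt(d/H)`.
- *Encoder residual wiring*: the closing layer norm takes `IO2 + X` — the
  block input, exactly as the architecture family's equations print it —
  by default; `post_ln_residual = "io2"` selects the conventional variant.
- *Token pooling before the classifier* is a flatten, not a mean-pool.
- *Branch fusion* is channel-wise concatenation after aligning both branch
  outputs to `d_out` positions by adaptive max-pooling (window
  `floor(L/d_out)`, surplus tail positions dropped).
- *SE block convolutions* are 1x1 over the modality axis (the spatial
  dimensions are already summarized by the global pool; with L = 1 the gate
  degenerates to a single scalar, which stays well-defined). A ReLU sits
  between each pair of convolutions.
- *Distillation*: natural logarithms throughout (divergences in nats), no
  temperature, probabilities clamped at 1e-12 before logs; the teacher is
  detached by construction (no gradient path exists into frozen parts).
- *Halting* uses a strict `<`, which makes Speed 0 reproduce all-final
  routing identically — asserted by test.
- *Input normalization*: per-epoch, per-channel z-scoring (`normalize =
  TRUE`). Raw-amplitude mode is available for pipelines that must not
  rescale.
- *Optimizer*: Adam (lr 1e-3 default, overridable), seeded shuffling; batch
  norm uses momentum 0.1 with eval-mode statistics in all frozen paths, so
  stage 2 and inference are deterministic.
- *Conv biases* ahead of batch norm are redundant (the normalization removes
  per-channel shifts); they are retained for structural uniformity and their
  gradients are exactly zero along those directions.

## Problem sizes used by the shipped experiments

The test suite trains the reduced configuration on 1500 synthetic epochs
(tiers 50/30/20 percent) for 22 stage-1 and 25 stage-2 passes at batch 64 —
a few minutes on one CPU — and evaluates the Speed sweep on the same 1500
epochs, mirroring how the full-scale experiments report routing and cost on
the dataset at hand. A held-out set is also generated in the examples to
illustrate the (expected, and observed) generalization gap of a desk-scale
run. The learnability check trains on 300 single-tier epochs; oracle
equivalence suites use 1000 random distributions/confusion tables; spectral
fidelity uses 50 epochs per stage.

## Known limitations

- The encoder uses no positional encoding (none is part of the printed
  architecture); token order information enters only through the flatten
  before the classifier.
- Per-modality extractor hyperparameters are shared across modalities; the
  config accepts only one width set for all three.
- Training is plain R (BLAS matmuls, hand-derived gradients): perfectly
  adequate at desk scale, not a competitor to GPU frameworks at full scale.
- EDF support covers the 16-bit signal format with per-signal rates;
  hypnograms are read from two-column CSV, not from embedded EDF+
  annotations.
- Subject-wise cross-validation splits are supported through per-epoch
  subject ids, but no cross-validation campaign is wired in.
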