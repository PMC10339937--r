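---
title: "Temporal shift modules for clip classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal shift modules for clip classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftclip)
```

## The problem

Aggressive interactions in group-housed animals (biting, knocking,
treading, chasing in pigs are the motivating case) are short, fast,
multi-animal events. A single frame rarely separates them from benign
contact: the discriminative signal is *displacement over time* —
coordinated, high-amplitude motion of two or more animals. Recognizing
them from overhead video therefore needs spatio-temporal features, but
full 3D convolutional networks are expensive, and CNN→LSTM hybrids
discard low-level temporal structure before any temporal fusion happens.

## The temporal shift operator

The temporal shift module (TSM) gives a plain 2D CNN temporal modeling
ability at *zero parameter and zero FLOP cost*. Given a clip tensor with
`T` frames and `C` channels, the operator moves the first
`k = floor(C·f/2)` channels one step forward in time (frame `t` receives
frame `t−1`'s content), the next `k` channels one step backward, and
leaves the remaining channels untouched; vacated boundary frames are
zero-filled. A 2D convolution applied afterwards mixes current-frame and
neighboring-frame features, which is the same multiply-accumulate a
temporal (kernel-3) convolution would perform. The package exposes this
identity directly: `shift_decompose_conv()` computes
`Y_i = w1·X_{i−1} + w2·X_i + w3·X_{i+1}` as shift-then-accumulate, and
the tests verify it against a directly computed zero-padded
cross-correlation to 1e-12.

The total shifted fraction `f` defaults to **1/4** — the bidirectional
proportion is read as the *total* fraction (1/8 per direction), the
convention of the original TSM line of work this package follows. Large
fractions degrade spatial modeling (most of each feature map should stay
frame-aligned); zero disables temporal modeling entirely and is
bit-for-bit equivalent to the unmodified network, which the tests assert.

Channel assignment (first `k` forward, next `k` backward) is an
arbitrary but frozen convention; nothing in the method prescribes which
channels shift, only how many. With non-divisible `C` the floor rule
leaves leftover channels unshifted. Only the offline (bidirectional)
variant is implemented: clips are recorded, so future frames are
available. Shifting is always confined within one clip — the network
layer receives the true frame count `T` explicitly and never infers it
from the batch.

## Insertion into residual-family backbones

`build_backbone()` constructs ResNet50, ResNeXt50 (32×4d), ConvNeXt-tiny
and DenseNet201 as explicit layer graphs — every convolution,
normalization, activation and linear layer with its exact shape — so
`count_parameters()` computes counts from the architecture rather than a
table. With a 2-class head the counts land on 23.51 M, 22.98 M and
18.10 M for ResNet50, ResNeXt50 and DenseNet201 respectively.
ConvNeXt-tiny computes 27.82 M; the reference literature for this
configuration prints 49.46 M, which does not correspond to any standard
ConvNeXt-tiny variant we can reconstruct, so the package implements the
standard architecture and treats that figure as unverifiable rather than
a target. ResNeXt50 is fixed at cardinality 32 / base width 4 — the
standard 32×4d configuration, the one consistent with 22.98 M.

`insert_tsm()` places the shift in front of the first convolution of
every block's transformation branch. Identity/skip paths are never
shifted, so unmodified per-frame content reaches deeper layers. Two
families need documented equivalents of "residual branch":

- **DenseNet** has concatenative reuse rather than addition; the shift
  sits just before the 1×1 convolution inside each dense layer's
  composite function (BN–ReLU–**shift**–conv1×1–BN–ReLU–conv3×3), so the
  concatenated pass-through features remain unshifted.
- **ConvNeXt** blocks start with the 7×7 depth-wise convolution, so the
  shift precedes it.

Insertion adds exactly zero trainable parameters in all four families
(asserted), and double insertion is rejected. The head in every family
is global average pooling over space, frame-mean temporal consensus
(`temporal_consensus_head()`; the aggregation step is not prescribed by
the method, and the arithmetic frame mean is the simplest
order-respecting choice at the logit level), then the family's
classifier. ImageNet-1K pretrained weights are an optional *input* (the
`pretrained` flag records the intent); they are never computed or
downloaded here, and all tests run from seeded random initialization.

The Grad-CAM layer registry resolves "last activation of the third block
of the fifth stage" per family: the post-addition ReLU for
ResNet50/ResNeXt50 (`stage5.block3.relu3`), the block GELU for
ConvNeXt-tiny, and the last dense-layer activation of the final stage
for DenseNet201.

## Clip ingestion and splitting

Clips are stored as directories of numbered PNG frames — the canonical,
codec-free format for this package. No video-codec binding (ffmpeg or
similar) is available to R in this environment, so MP4/AVI containers
are rejected with guidance to decode to frame directories first; this is
a convenience path deliberately narrowed, not a change in the data
model. Decoding is deterministic (bit-identical re-reads) and frames are
sampled at uniform intervals (`floor` of a linear index grid — strictly
increasing, no duplication, and a hard error rather than padding when a
clip is short). Values are in `[0, 1]` as decoded; bilinear rescaling to
a target size is applied when the plan requests it. Full-scale pipelines
rescale source video to 720×480 before clipping; the synthetic pipeline
generates at its native size and keeps it.

`split_manifest()` assigns train/validation/test at 6:2:2, stratified by
label, with `floor(n·r/Σr)` per split and the remainder to train; a
balanced 10,440-clip manifest yields 6264/2088/2088. The split is a
seeded random permutation (the reference procedure does not state
whether its split was random or stratified; stratified-random with an
explicit seed is the reproducible default). An optional `group` argument
keeps clips cut from the same source video in one split, for the case
where clips from one aggression bout should not straddle splits.

## The synthetic generator: what it emulates and what it does not

`generate_clip()` renders 1-s, 25-fps, 112×112 grayscale clips of
anti-aliased bright discs on a dark background. Label 1 (the aggression
proxy) shows two agents converging and then exhibiting coupled
high-amplitude displacement (shared rapid jitter plus push–pull along
the contact axis, amplitude 3 px/frame); label 0 shows independent slow
drift (0.8 ± 0.3 px/frame versus 4 ± 1 px/frame during aggressive
convergence). Defaults were chosen once as a plausible desk-scale
analogue — agents span roughly a fifth of the frame, aggressive motion
is about one body radius per few frames, additive pixel noise
(sd 0.02) is small against the disc/background contrast — and the class
signal lives in displacement statistics, not appearance: the per-frame
intensity histograms of the two classes overlap (asserted with a bounded
histogram distance).

What passing tests on this generator show: the pipeline trains, the
shift operator carries temporal information, metrics and explanations
are computed correctly. What they do not show: robustness to occlusion,
lighting, animal adhesion or appearance variation — nothing here renders
a pig. Results on synthetic clips are statements about the machinery,
not about farm accuracy.

`generate_direction_task()` isolates temporal modeling completely: label
0 clips translate a blob left-to-right; each label 1 clip is the *exact
frame reversal* of a label 0 clip, noise included. The two members of a
pair contain the identical multiset of frames, so any classifier whose
prediction is invariant to frame order — in particular a per-frame 2D
CNN with frame-mean consensus — has exactly chance expected accuracy by
construction. Both generators can write frame directories or keep
rendered tensors in an in-memory store attached to the manifest; the
pixel content is identical (tested), and the in-memory path simply
avoids writing thousands of PNGs during the experiment.

## Training and evaluation

`train_config()` defaults to the full-scale recipe: SGD with momentum
0.9, initial learning rate 0.00125, weight decay 1e-4, batch size 8,
60 epochs, and per-step global L2 gradient-norm clipping at 40. Choices
the recipe leaves open are fixed as follows: the loss is two-class
cross-entropy on consensus logits; the schedule is constant (only an
*initial* rate is specified upstream; no decay rule is described);
momentum is the conventional coupled formulation
`v ← m·v + (g + wd·θ)`, `θ ← θ − lr·v`, with clipping applied to the raw
loss gradient before the decay term is added (single-step oracle in the
tests); weight decay applies to every trainable tensor. Evaluation makes
one prediction per clip (argmax of consensus logits, ties broken toward
the negative class) and computes accuracy, recall, precision and F1 from
TP/FP/TN/FN exactly, with any zero-denominator metric defined as 0.
Per-clip latency is recorded for information only — it is
hardware-bound and never a test gate.

The compute engine behind the trainable nets (im2col-lowered 2D
convolution through BLAS, batch normalization, the batched shift layer
and its adjoint) is implemented in the package and validated by
finite-difference gradient checks; a leading parameter-free
average-pooling layer is memoized per clip across epochs, which changes
nothing numerically.

## The temporal-discrimination experiment

`temporal_discrimination_experiment()` trains two arms from identical
seeded initializations on the direction task (400 training / 100 test
clips at 112×112, T = 25, reversed pairs never straddling the split): a
small TSM-inserted residual net, and the identical net without TSM. The
toy net pools the input 8× on entry, applies a strided 3×3 convolution
and two identity-shortcut residual blocks at 7×7 resolution (8
channels), then global average pooling, frame-mean consensus and a
linear head — about 2,500 parameters, sized so an arm trains in a couple
of CPU-minutes. Training runs the standard recipe with the step budget
scaled to the toy problem: 20 epochs, learning rate raised to 0.05
(appropriate for a small batch-normalized net at this batch size; the
full-scale rate of 0.00125 is tuned to fine-tuning pretrained
backbones).

The no-TSM arm is frame-order invariant end to end, so on the paired
test set it scores exactly 50% regardless of training. The TSM arm can
read motion direction from the shifted channels and reaches ≥ 90%
(typically 100%) across seeds; with `shift_fraction = 0` the two arms
are bit-identical, which is the degenerate control. The acceptance suite
asserts the separation with a 3-seed majority rule.

## Grad-CAM for clips

`gradcam_clip()` computes, per frame, the gradient of the clip-level
class score (the consensus logit, pre-softmax) with respect to the
target layer's activations, pools it over space to one weight per
channel, rectifies the weighted channel sum, bilinearly upsamples to the
input frame size, and min–max normalizes over the whole clip. A clip
with no gradient signal yields all-zero maps (the zero-range guard).
One heatmap is produced per input frame; the display subset is every
fifth frame — indices 0, 5, 10, 15, 20 of a 25-frame clip — and
`render_heatmap_overlay()` writes both the full heatmap sequence (as a
frame directory, like every clip here) and the display panels. On a
one-convolution model the maps equal the hand-computed gradient-weighted
activation map exactly (tested).

## Numerical choices and degenerate inputs

- Batch-norm epsilon 1e-5, running-stat momentum 0.1 (biased batch
  variance in the normalizer, unbiased in the running estimate).
- Shift with `T = 1`: both neighbors are out of range, so shifted
  channels become all-zero.
- `floor` rules everywhere an integer is derived from a fraction
  (shifted channels per direction, split sizes, sampling indices), with
  remainders documented (unshifted channels; train split).
- Prediction ties go to the negative class, so an all-zero model reports
  zero false positives rather than coin-flips.
- Argmax/consensus are deterministic; all stochastic stages (weight
  initialization, shuffling, scene generation) consume explicit seeds,
  and generators restore the caller's RNG state.

## Problem sizes used by the test and acceptance runs

Parameter accounting and split arithmetic run at full scale (they are
cheap and exact). The trainable experiments run at the desk scale
described above — 500 synthetic clips per seed, 3 seeds, both arms —
chosen so the complete suite runs on one CPU core in well under half an
hour. Full-scale claims (accuracies on real farm video, per-clip
latency on GPU hardware) are out of scope by design: they require the
original 10,440-clip dataset and GPU training, and no number reported by
this package depends on them.

## Known limitations

- The four large backbones are structural graphs with exact parameter
  accounting, insertion points and layer registry; their forward pass is
  not materialized (no pretrained weights are obtainable offline, and
  CPU training at 23 M parameters is not a sensible test surface).
  The trainable path exercises the identical block/inserter machinery.
- PNG frame directories are the only decode path; video containers must
  be pre-decoded.
- The synthetic generator models displacement statistics, not
  appearance; transfer of any accuracy number to real footage is
  explicitly not claimed.
- ConvNeXt-tiny's published 49.46 M parameter figure could not be
  reconstructed from any standard variant; the package reports the
  computed 27.82 M for the standard architecture.
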