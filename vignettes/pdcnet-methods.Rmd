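---
title: "Methods: parallel dilated convolutions for low-contrast lesion segmentation"
author: "pdcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parallel dilated convolutions for low-contrast lesion segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcnet)
```

## The segmentation problem

Small lesions in grayscale medical images — pituitary adenomas in brain MRI
are the motivating case — present three linked difficulties: the lesion
occupies a tiny fraction of the image (severe class imbalance), its outline
is irregular, and its intensity contrast against surrounding tissue is low.
`pdcnet` implements an encoder–decoder network specialised for this regime,
together with the loss, metrics, training protocol and a synthetic phantom
generator that reproduces the regime so every component can be exercised
and tested without clinical data.

## Architecture

The backbone is a U-Net-style encoder–decoder. Each encoder level applies a
*basic convolution* (one 3×3 convolution, batch normalization, ReLU,
DropBlock) followed by a **parallel dilated convolutional module (PDCM)**,
the two together wrapped in a residual shortcut; a 2×2 max-pool then halves
the spatial size while the channel width doubles. The decoder mirrors this
with 2×2 transposed convolutions (spatial size doubles), concatenation with
the same-resolution encoder features, and the same residual level block.
A 1×1 convolution plus sigmoid produces the per-pixel lesion probability.

### PDCM

The module runs five parallel branches over its input:

1. a 1×1 convolution that maps the input to the module width (this output,
   `F1`, doubles as the channel-matched module input for the other
   branches);
2. –4. three 3×3 convolutions with dilation rates 2, 4 and 6, giving
   effective receptive fields of 5, 9 and 13 pixels at one level
   (`(k-1)·d + 1` for kernel `k`, dilation `d`);
5. a channel attention branch.

With *progressive fusion* (`variant = "pdcm_previous"`), branch `k ≥ 2`
receives `F(k-1) + F1` — the previous branch output added to the projected
input — so small-receptive-field evidence feeds the larger scales. Note
that for branch 2 the previous output *is* `F1`, so its input is `2·F1`;
this is the literal reading of the progressive-fusion rule with the 1×1
output standing in for the raw input, which cannot be added directly
because its channel count differs. Without fusion
(`"pdcm_no_previous"`) every branch sees `F1` alone — same parameters,
different dataflow. The module output is the elementwise sum
`F1 + F2 + F3 + F4 + F5`. The `"+"` here is genuine addition, not
concatenation: all branches share the module width, and the same `+`
accumulates the output sum and the residual shortcuts.

Small dilation rates (2/4/6 rather than the 6/12/18 common in atrous
pyramids) are deliberate: with a lesion of a dozen pixels across, large
dilations produce gridding and sample mostly background.

### Channel attention

The fifth branch is squeeze-excitation-style gating: global average pool to
one value per channel, a channel-reducing dense map (ratio 8 by default),
ReLU, a channel-restoring map and a sigmoid. The resulting per-channel
weights in (0, 1) rescale the branch input. Because the published block
diagram specifies only "pooling, channel convolution, sigmoid", this
minimal squeeze-excitation form was adopted; the reduction ratio is exposed
in `BlockConfig`.

### Residual wrapping

Each level's `[basic conv → PDCM]` pair is wrapped jointly by an additive
shortcut. When the level changes the channel count the shortcut passes
through a 1×1 projection convolution (no batch norm on the shortcut);
otherwise it is the identity. Wrapping the pair jointly (rather than the
PDCM alone) follows the architectural description of one level as a basic
convolution and a PDCM connected by residuals.

## Loss and metrics

Training minimises the soft Dice loss
`1 − 2Σyŷ / (Σy² + Σŷ²)` per image, averaged over the batch. Per-image
averaging prevents large lesions from dominating a batch. A smoothing
constant `eps` (default `1e-6`) is added to numerator and denominator so
lesion-free images are well defined; `eps = 0` recovers the exact formula
and is used by the closed-form tests.

Evaluation reports four confusion-count metrics at threshold 0.5.
**Important:** the sensitivity implemented by default is `TP/(TP+FP)` —
exactly the formula printed in the reference definitions, which
conventional terminology would call *precision*. The package follows the
printed formula so its numbers are comparable with the source tables, and
exposes `standard = TRUE` for the conventional recall `TP/(TP+FN)`. The
remaining metrics are uncontroversial: specificity `TN/(FP+TN)`, Dice
`2TP/(2TP+FN+FP)` and IoU `TP/(TP+FN+FP)` (with the exact identity
`IoU = Dice/(2−Dice)`). When a denominator is empty (e.g. empty ground
truth and empty prediction) the metrics return 1 with a warning — perfect
agreement on emptiness — configurable via the `degenerate` argument.

## Training protocol

Defaults follow the reference protocol: Adam with learning rate `1e-5`,
`beta2 = 0.999` (the protocol's "momentum 0.999" is read as the
second-moment decay, with the standard `beta1 = 0.9`), batch size 16,
300 epochs, DropBlock rate 0.1, and checkpoint selection by *minimum
validation loss* — with a dip-then-rise validation curve the saved model is
the dip, never the last epoch. No data augmentation is applied and early
stopping is off by default (a `patience` option exists). All randomness
(initialisation, shuffling, DropBlock) is governed by explicit seeds, and
a fixed seed reproduces checkpoints bit-for-bit on one machine.

DropBlock details: the drop probability 0.1 is interpreted as the
DropBlock rate (the only structured dropout the architecture mentions),
with block size 5, applied after each basic convolution block in the
encoder/decoder and active only in training mode.

## Implementation notes

No deep-learning framework is used: convolution (with dilation), batch
normalization, max-pooling, transposed convolution, channel attention,
DropBlock, backpropagation and Adam are implemented in the package, with
the convolution/pooling kernels in compiled code (im2col plus GEMM). Every
layer's analytic gradient is verified against central differences in the
test suite at tolerances of about `1e-4` (the full network) down to
`1e-10` (individual layers). Batch norm uses biased batch variance in
training and running statistics (momentum 0.1) in evaluation; evaluation
mode is fully deterministic.

Numerical choices worth recording: He-normal weight initialisation
(fan-in); Adam epsilon `1e-8`; batch-norm epsilon `1e-5`; dice-loss
smoothing `1e-6`; binarization threshold 0.5; max-pool ties resolve to the
first maximum in scan order; the decoder's first convolution maps the
concatenated (skip + upsampled) channels back to the level's nominal
width; inputs must be divisible by `2^(depth−1)`, and the prediction
exporter pads (reflect or zero) to the next multiple and crops back
exactly.

## The phantom generator

`generatePhantom()` emulates the data regime, not the anatomy: an
elliptical "head" with low-frequency cosine texture on a dark background;
one star-convex lesion whose boundary radius is perturbed by random
low-order Fourier coefficients (irregular outline), placed inside the head
eroded by the lesion radius; intensity raised by `contrastDelta` (default
0.12, low contrast); Gaussian noise (`sigma = 0.05`); 8-bit quantisation so
PNG round trips are exact. The lesion area fraction is rejection-sampled
into 0.5–3% of the image — far smaller than background, matching the class
imbalance — and masks are guaranteed single 4-connected components.
Splits use disjoint `(seed, index)` streams and the 3:1:1 train/val/test
ratio of the reference protocol (12/4/4 at desk scale).

What passing tests on phantoms do **not** show: real MRI bias fields,
k-space artefacts, inter-slice correlation, multi-lesion images, or
observer variability in annotations. The generator supports engineering
claims (the architecture trains, converges, and is measured correctly),
not clinical ones.

## Problem sizes used by the test suite

The suite runs at desk scale by choice: the overfit probe trains the
full model (depth 3, base width 8) on eight 32×32 phantoms for 300
full-batch steps and expects training Dice ≥ 0.95; the end-to-end pipeline
uses a 12/4/4 split at 64×64 with a few epochs to verify wiring rather
than accuracy; gradient checks use depth-2, width-2 networks on 8×8
inputs. The published headline numbers (Sensitivity 0.9092, Specificity
0.9968, Dice 0.8845, IoU 0.7943) were measured on a private 38-patient
clinical dataset and are not reproducible without it — the package
reproduces the *method* and verifies it property-by-property instead.
(Published accounts of this architecture also quote slightly different
headline Dice values, 88.34–88.45%, in different places — a further reason
to treat properties rather than any single number as the target.)

## Known limitations

- 2-D single-channel only; no volumetric variant or multi-modal fusion.
- The channel-attention internals and DropBlock block size follow standard
  choices where the source is not fully specified; both are configurable.
- Pure-R + BLAS execution is single-device and CPU-bound; the
  configuration defaults (base width 16) are sized for that.
- Only the architecture's own ablation variants are implemented; no
  third-party comparison networks.
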