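---
title: "Model, training procedure and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, training procedure and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pearnet` implements a one-stage anchor-based pear detector with a
CNN–transformer hybrid neck, a synthetic orchard-scene generator, a
stochastic-gradient training loop and a stratified evaluation stack. This
vignette records the model assumptions, the tunable parameters and their
defaults, the numerical choices, and the places where the design was
genuinely open and a decision had to be made.

## The detection model

The backbone is a CSP-Darknet: a Focus block (lossless space-to-depth
slicing followed by a convolution) halves the spatial resolution, four
stride-2 CBS blocks (convolution + batch normalization + SiLU) build a
feature hierarchy, CSP1 blocks with `n` residual units extract features at
each level, and spatial pyramid pooling (same-padding max pools of 5, 9, 13)
enlarges the receptive field at the deepest level. Channel widths and block
repeats scale with `width_multiple` (0.50) and `depth_multiple` (0.33) —
the "small" sub-version. All widths round to multiples of 8.

The neck is a path-aggregation network: a top-down pass upsamples deep
features and concatenates them with backbone skips, a bottom-up pass
downsamples again, producing maps at strides 8, 16, 32 (the
high/medium/low-resolution paths P1, P2, P3). The head is an anchor-based
1×1 convolution per scale predicting, per anchor and cell, box offsets, an
objectness logit and class logits. Offsets decode as
`xy = (2σ(t) − 0.5 + grid)·stride`, `wh = (2σ(t))²·anchor`.

Three modifications define the full (`FP`) variant; each can be enabled
separately for ablation:

* **Skip connections (`SC`).** Both new skips originate at the fusion point
  that feeds P1's feature-extraction block. One routes around that block
  (one bypassed module) into the P2 fusion; the other routes around the P1
  and P2 extraction blocks (two bypassed modules) into the P3 fusion. They
  are carried by 1×1 stride-2 CBS convolutions and merged by addition, so
  the stock channel plan is untouched. Rationale: merging by addition is
  the reading consistent with "bypassing one and two feature-extraction
  modules" while keeping the transformer encoder insertable at P3 (it is
  shape-preserving, so its input width must equal the stock CSP2's).
* **Transformer encoder (`TE`).** A shape-preserving block of multi-head
  self-attention over the flattened spatial grid followed by a
  convolutional feed-forward sublayer (two pointwise convolutions,
  expansion ratio 4), both with residual additions, batch normalization
  before each sublayer, and dropout (default 0.1) after attention and the
  feed-forward. It replaces the CSP2 of the low-resolution path P3. The
  embedding width equals the channel count at the insertion point; heads
  default to 4; there is **no positional encoding** — self-attention is
  then permutation-equivariant over cells, which the tests exploit.
* **Fusion CSP (`TC`).** CSP-FF replaces the CSP2 of the medium-resolution
  path P2. Its two parallel paths are a convolutional path (1×1 then 3×3
  CBS; local features, the X input) and a transformer path (1×1 CBS then a
  transformer encoder; global features, the Y input), fused by attentional
  feature fusion and balanced by a final 1×1 convolution. AFF computes
  `M(X+Y)·X + (1−M(X+Y))·Y` where `M` is a sigmoid channel attention with
  a local pointwise-bottleneck branch (reduction ratio 4) and a global
  branch on the spatially pooled context; the output is an elementwise
  convex combination of its inputs.

Anchors default to the stock COCO priors ((10,13)…(373,326) pixels at a
640 input), rescaled linearly with the input size, and are overridable in
the configuration. The pear task is single-class.

## Losses

Box regression uses the EIoU loss: `1 − IoU` plus center-distance, width
and height penalties normalized by the smallest enclosing box (squared
diagonal, squared width, squared height respectively). It is zero iff the
boxes coincide, bounded below by `1 − IoU`, and invariant to joint
translation and scaling. All denominators carry an epsilon of 1e−7; a pair
of boxes degenerate at a single point is defined to have loss 0.

The composite training loss is `0.05·box + 1.0·objectness + 0.5·class`
(configurable): the box component is the mean EIoU over assigned anchors,
objectness is binary cross-entropy over every anchor-cell with the detached
decoded IoU as the positive target (scale-balanced 4.0/1.0/0.4), and class
is binary cross-entropy on assigned entries. Targets are assigned by the
stock multi-anchor rule: an anchor matches when the width and height ratios
both lie within a factor 4, and each match claims the center cell plus up
to two neighboring cells whose fractional offset is within half a cell.

## Training

Defaults follow the standard field recipe for this detector family: SGD with momentum 0.937 and weight
decay 0.00048 (applied to convolution/linear weights only), batch of 8
images by gradient accumulation, 200 epochs, initial learning rate 0.01
cosine-annealed to 0.001, 640-pixel inputs, a 50-iteration linear warmup.
The wording that momentum "decayed to 1e−4" does not describe a meaningful
SGD setting; constant momentum with warmup is used instead. Divergence
(non-finite loss) aborts with a diagnostic. Per-epoch mean training loss
(total and components) and validation loss (total and box) are recorded;
the best-validation weights are retained. Augmentation (random left–right
and up–down flips, HSV jitter with bounds ±0.015 hue and ±0.7
saturation/value, 3×3 blur, four-image mosaic) is off by default and
enabled with `augment = TRUE`; operations are drawn at image-reading time.

**Normalization.** The engine forwards one image per pass and accumulates
gradients over the batch, so the batch dimension never exists inside a
layer. Under these conditions classic batch normalization is inconsistent:
training normalizes each map by its own statistics while evaluation would
use running averages, and a network trained this way learns to rely on
per-image normalization that the running averages cannot reproduce (in our
experiments evaluation-mode AP collapsed while training-mode decoding was
accurate; freezing the running estimates mid-training destabilized the
optimization because the layerwise mismatch compounds). The CBS blocks
therefore normalize by the current map's spatial statistics at **both**
training and evaluation time — instance-style normalization with the BN
affine parameters. Inference remains deterministic (the statistics depend
only on the image). Running estimates are still tracked and used only for
degenerate 1×1 maps.

## Synthetic scenes

The generator emulates the experimental axes of an in-field pear dataset,
not its photorealism: pears are radial-gradient ellipses (aspect 0.8–1.1,
hue 30–75°) over a leaf/branch-textured canopy; occluders (leaf blobs and
branch strips) cover each pear up to the scene specification's occlusion fraction; four
illumination regimes (weak/normal/strong/artificial) apply
brightness/gamma/color-cast transforms with mean brightness ordered weak <
normal < strong; side and bird's-eye viewpoints differ in background
gradient and branch orientation. The default radius mixture (25% small, 58%
medium, 17% large) reflects the size-stratum composition typical of in-field pear imagery
(small pears outnumber large roughly 3:2); the default of 15 pears per 640-px scene is a realistic density for
canopy photographs given that real images average ~45 annotations at much
higher optical resolution. Ground-truth boxes are the amodal (full-fruit)
extent clipped to image bounds — the generator can also emit visible-region
boxes, but amodal is the default since annotators box the whole fruit —
and pears whose post-clip radius falls below 5 px are omitted, mirroring
the annotation rule. Scenes are bit-reproducible from their seed.

Passing tests on these scenes demonstrates that the pipeline — rendering,
assignment, optimization, decoding, evaluation — is internally consistent
and can learn; it does not demonstrate field accuracy on real orchard
imagery, which depends on textures, backgrounds and annotation noise the
generator does not model.

## Problem sizes in the tests

The suite runs on one CPU, so simulations are scaled down: unit tests use
64-pixel inputs at quarter width; the learning sanity check trains the full
variant at quarter width on sixteen 96-pixel scenes of two large, unoccluded
pears for 40 epochs at batch 2 (320 optimizer iterations) and requires
training-set AP50 > 0.5 (measured 0.675 at the fixed seed); one structural
test runs a full-width forward pass at 640 to confirm the 80/40/20 head
grids. The FLOP profiler is exact arithmetic over the wiring (shape
propagation, no numerics), so it runs at full size everywhere.

## Numerical choices and degenerate inputs

* FLOPs are counted as 2 × multiply-accumulates over convolutions and
  matrix multiplications (attention included; normalization, activations
  and pooling are not MAC-bearing). This convention reproduces the printed
  16.4 GFLOPs of the stock small baseline at 640 to within 1%.
* He initialization for convolutions, Xavier for attention projections;
  head biases start the objectness prior at ~8 expected objects per image.
* IoU of a zero-area pair is 0; AP with no ground truth is undefined and
  reported as absent; 0/0 precision, recall and F1 are 0.
* Greedy NMS suppresses strictly-above-threshold overlaps; matching visits
  predictions in descending confidence and lets each claim its best-IoU
  unmatched ground truth.
* The precision–recall curve integrates with all-point (continuous)
  interpolation via the monotone precision envelope; 11-point interpolation
  is available behind a flag. Size-class boundaries fall in the lower class
  (radius exactly 10 px is small, exactly 25 px is medium).
* Unmatched detections are assigned to size strata by their own size class;
  matched ones inherit their ground truth's stratum.
* Annotations are the normalized center format; a corner-format import shim
  handles `class x1 y1 x2 y2` pixel lines. Out-of-range boxes are clipped
  to the unit square with a warning count.
* The near-duplicate filter is a Harris-corner detector with binary
  intensity-comparison descriptors matched by Hamming distance (500
  keypoints, match-ratio threshold 0.6 by default) scanned greedily and
  sequentially; no canonical value exists for the match-ratio cutoff of such
  a cleanup step, so these are declared defaults.

## Known limitations

* Throughput: training is practical at reduced resolution/width (desk
  scale); full 640-pixel, 200-epoch training is out of reach on one CPU,
  and the headline field accuracies of the method (e.g., AP50 ≈ 96% on real
  orchard data) require the original dataset and GPU-scale training, which
  this package deliberately does not claim to reproduce.
* Instance-style normalization (see above) departs from stock batch
  normalization; with a true batched engine the stock behaviour would be
  preferable.
* The synthetic renderer is a controllable test surface; transfer of any
  trained weights to real imagery is not expected.
* Mosaic augmentation composes exact quadrants (scale 0.5 each) rather than
  a randomly shifted center crop.
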