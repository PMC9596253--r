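---
title: "Methods: cascaded localization and fine segmentation of small CT tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascaded localization and fine segmentation of small CT tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ctcascade)
```

## The problem and the approach

Small renal tumors occupy a tiny fraction of an abdominal CT volume: a
handful of axial slices, and within those slices a blob of at most a few
hundred pixels. A segmentation network shown whole slices therefore spends
almost all of its capacity and its gradient signal on background, and small
lesions are diluted away. `ctcascade` implements the standard remedy as a
two-stage cascade:

1. **Localization (stage A1).** A slice-level detector scans every axial
   slice and proposes axis-aligned boxes around tumor candidates. Each box
   is expanded by a 10-pixel margin on all four sides (clamped at the slice
   border) and cropped out. The margin-expanded crop *is* the coarse
   segmentation: it bounds where tumor can be without deciding any pixel.
2. **Fine segmentation (stage A2).** A shallow U-shaped encoder–decoder
   with an embedded feature pyramid maps each 3-channel crop to a 2-class
   (background/tumor) logit map at full crop resolution. Predicted masks
   are pasted back at their crop offsets; overlapping crops are unioned.

Slices with no detections remain all-background. Evaluation uses the
overlap metrics Dice, Jaccard (IoU), precision, and recall between the
predicted and true tumor pixel sets.

## Stage A1: the grid detector

Localization is treated as a per-cell binary classification with box
regression. The slice (windowed to 8 bits, rescaled to $[0,1]$, grayscale
replicated to 3 channels) passes through an optional *focus* transform — a
lossless space-to-depth rearrangement that moves the four pixel parities
into channels, halving resolution — and a small stack of 3×3
convolution / leaky-ReLU / max-pool blocks down to a grid whose cells are
`grid_stride` (default 8) pixels. A 1×1 head emits five numbers per cell:
an objectness logit, the tumor-center offset within the cell (through a
sigmoid), and log-width/log-height relative to the stride.

The loss is binary cross-entropy on objectness over all cells plus squared
error on the box parameters at positive cells (the cell containing a
ground-truth box center). Two scale choices matter on our data and are
deliberate:

* positive cells are rare (at most a couple per 8×8 grid, none on most
  slices), so the positive BCE term is up-weighted (`pos_weight = 8`);
* the box term is normalized by the total cell count, like the objectness
  term, not by the positive count. Normalizing by the (often single)
  positive cell makes the box gradient two orders of magnitude larger than
  the classification gradient and reliably destabilizes SGD at the default
  learning rate.

The backbone uses leaky ReLU (slope 0.1) rather than plain ReLU: with the
sparse, spiky objectness gradients, plain ReLU units die in the first few
epochs and the head collapses to a constant map. The objectness bias is
initialized to $-3$, near the logit of the positive-cell prior, so early
training is not dominated by driving scores down.

During training each drawn slice is replaced, with probability 0.5, by a
*mosaic*: four training slices rescaled into the four quadrants around a
random center, masks transformed identically and boxes recomputed from the
transformed mask. In our experiments mosaic costs overfit-speed but adds
measurable slice-level recall on held-out volumes (0.95 vs 0.83 at
20 epochs under identical seeds), which is what the cascade needs.

No non-maximum suppression is applied by default: every above-threshold box
is cropped and segmented and the results are unioned, which is conservative
for recall; greedy NMS is available as a flag. A ground-truth **oracle
detector** (`oracle_detect()`: component boxes with score 1) isolates stage
A2 in tests and experiments.

## Stage A2: shallow U-Net with an embedded feature pyramid

The encoder has `depth + 1 = 4` stages of two 3×3 convolutions with ReLU,
2×2 max pooling between stages, and channel widths doubling from
`base_channels` (64, 128, 256, 512 at the defaults). Three downsamplings —
one stage fewer than the classic U-Net — keep the parameter count small
enough not to overfit small tumor datasets, and one more stage
(`depth = 4`) is exactly the "non-shallow" ablation arm.

The stage outputs form the bottom-up pathway of a feature pyramid: each is
projected to `fpn_channels` by a 1×1 lateral convolution, and from the
coarsest level each map is 2×-bilinearly-upsampled and added pixel-by-pixel
to the next finer lateral map until the finest level. The merged maps
*replace* the plain skip connections: the decoder at each level upsamples
(bilinear 2×), applies a 2×2 convolution that halves the channels (padded
bottom/right so spatial size is preserved), fuses the pyramid map — by
channel concatenation (default) or by projected addition — and applies two
3×3 conv + ReLU. A final 1×1 convolution maps to the 2 class logits, so a
$(H, W, 3)$ input yields a $(H, W, 2)$ output whenever $H$ and $W$ are
divisible by $2^{\text{depth}}$; callers pad with `pad_to_multiple()`
(reflective, bottom/right) and crop back.

Where the pyramid enters the decoder, and the lateral width, are genuinely
open design points: published descriptions of embedded pyramids in U-shaped
networks rarely pin them down. Both are configurable
(`fpn_fusion`, `fpn_channels`, default concatenation at width 128); with
`use_fpn = FALSE` the network degrades to a plain U-Net, which is the
no-FPN ablation arm.

The decision rule is a per-pixel softmax with tumor declared where its
probability strictly exceeds 0.5; an exact tie goes to background. This is
the conservative direction for false positives and makes the all-zero logit
map predict background everywhere.

## Training

The loss is the unweighted pixel-mean cross-entropy
$L = -\sum_i p(x_i)\log q(x_i)$ with $q$ the softmax of the logits,
computed in log-sum-exp form. Despite the tumor/background imbalance, no
class weighting is applied by default (a weight vector is exposed);
margin-cropping itself removes most of the imbalance, which is one more
argument for the cascade. Optimization is small-batch SGD with momentum
0.9, learning rate 0.01, weight decay 0.0005, batch size 2, and no
schedule; the mean over each mini-batch's per-sample gradients is used.
A global gradient-norm ceiling (`clip_norm = 5`) guards each step: plain
SGD at this learning rate occasionally takes an exploding step on an
unlucky batch and diverges to NaN, and clipping the joint norm leaves
healthy updates untouched while capping the pathological ones.
Training records the mean loss per epoch and, every `eval_every`
iterations, the tumor-class Jaccard on an evaluation set with pixel counts
pooled across the set — the IoU convergence curve.

All randomness (initialization, shuffling, mosaic draws, phantom
generation) is derived from explicit seeds through an RNG-state-preserving
helper, so every stage reruns bit-identically; He-normal initialization is
used throughout. The convolution engine (stride-1 convolution as
im2col + GEMM, 2×2 max pooling, bilinear 2× upsampling with exact
adjoints) is compiled C++ with hand-derived backward passes, verified
against finite differences in the test suite.

## The phantom generator

Real kidney CT with voxel-level tumor labels cannot ship with a package, so
every stage is exercised on synthetic phantoms that emulate the geometry
the cascade exploits: a large ellipsoidal organ (intensity 80–120) on a
dark background (0–20), containing one small bright tumor blob (140–180)
placed strictly inside the organ. The tumor is a discretized spheroid with
in-plane radius drawn from 3–6 px and through-plane extent set so tumor
voxels span roughly `tumor_slice_fraction` (default 0.3) of the slices —
the "minority of slices" regime; its boundary radius is perturbed by a
low-order mixture of direction harmonics scaled by `irregularity` (default
0.3) to mimic irregular lesion outlines. Gaussian noise (sd 5, pre-window
units) is added last. The default abdominal window (level 40, width 400)
renders organ and tumor distinguishable but not trivially separated from
the noise floor.

What the phantoms do *not* emulate: textured parenchyma, partial-volume
effects, reconstruction kernels, neighboring organs of similar intensity,
or multi-focal disease by default. Passing the end-to-end tests therefore
demonstrates that the cascade's plumbing, losses, and optimization are
correct and that the architecture can learn this class of
localize-then-delineate problems — not that it reaches any particular
accuracy on clinical CT.

## Problem sizes and defaults of the shipped experiments

The package's experiment entry points use sizes chosen so a complete run is
comfortable on a single CPU while leaving the conclusions qualitatively
stable:

* `run_phantom_experiment()`: 30 training / 10 held-out volumes of
  16×64×64; detector trained 20 epochs (threshold 0.35); fine network at
  `base_channels = 24`, `fpn_channels = 48`, trained 24 epochs on the
  ground-truth margin crops. At these sizes the held-out tumor-slice mean
  Dice lands around 0.75 with locator slice recall above 0.9, and the
  evaluation IoU curve rises from 0 to a plateau above 0.9.
* the ablation harness at reduced width and epochs (`base_channels = 16`,
  8 epochs), on the same 30/10 split, with volume-level *pooled* metrics:
  per-tumor-slice averages would let the no-locator arm off the hook for
  its false positives on the three quarters of slices that contain no
  tumor, which is exactly the cost the locator exists to remove.
  Directions, not absolute values, are the point of these runs.

The no-locator arm deserves two design notes. First, a pipeline without
a localization stage has no slice-selection mechanism, so it trains on
every slice it sees; that is the configuration toggled here. One can
instead pre-filter the training slices by the ground-truth tumor flag —
but that flag *is* localization information, injected by hand, and the
resulting hybrid is not a no-localization pipeline. On these
high-contrast phantoms the hybrid is in fact competitive with the full
cascade (the phantom background is far simpler than real CT, so
whole-slice false positives are rare once training sees only tumor
slices); the comparison shipped here keeps the toggle clean instead.
Second, the arms' training sets differ in size by construction (every
slice vs only the tumor crops), so by default the harness matches the
number of optimizer steps across arms (`match_steps`) rather than the
number of passes over unequal datasets; under equal *epochs* at this
scale the two arms land within noise of each other, which compares
compute budgets more than pipelines.
* the default-width (64-channel) network is exercised in the overfit test:
  8 ground-truth crops to ≥99% pixel accuracy, reached in well under 200
  iterations.

Evaluation policy: metrics are averaged per slice over slices with
non-empty ground truth (where recall is defined); predictions on truly
tumor-free slices are counted separately as false-positive slices rather
than folded into the averages, and a pooled-pixel policy is available. The
cascade is evaluated on *all* slices of the held-out volumes — detector
misses score zero Dice on their slices and are not hidden.

## Numerical choices and degenerate inputs

* Overlap metrics with empty denominators (empty prediction for precision,
  empty truth for recall, both empty for Dice/Jaccard) return `NA` —
  explicitly undefined — never a silent 0 or 1.
* Windowing maps intensity $x$ to
  $\mathrm{round}\!\big(\mathrm{clip}((x - l + w/2)/w,\,0,\,1)\cdot(2^b-1)\big)$;
  it is monotone and idempotent under a full-scale re-window.
* Boxes are 0-based, half-open on max edges; component extraction is
  8-connected (a compiled two-pass union-find; the labeling available in
  the installed image stack is 4-connected).
* Bilinear upsampling uses half-pixel centers with clamped edges; its
  backward pass is the exact adjoint.
* `focus_transform()` is a pure permutation; its inverse is provided and
  tested, and its backward pass is that inverse.
* Reflect-padding never fabricates mask foreground: images and masks are
  padded by the same index reflection.

## Known limitations

* CPU-only; minutes-scale training at desk sizes, not suitable for
  clinical-resolution volumes without scaling work.
* The detector is a deliberately simple single-scale anchor-free grid: the
  cascade contract (detect → margin-crop → segment → paste back) is the
  reproducible content, not detector internals; multi-scale heads, anchors
  and path aggregation are out of scope.
* Labels are binarized to tumor/background; sub-type multi-class
  segmentation is out of scope.
* 2-D slice-wise processing only; no 3-D context across slices beyond the
  volume-level split and paste-back.
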