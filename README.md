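# ctcascade

Cascaded localization and fine segmentation of small tumors in CT volumes,
in pure R (with a compiled convolution core).

## The problem

Small renal tumors occupy a minority of a CT volume's axial slices, and
within those slices a blob of a few hundred pixels at most. A segmentation
network fed whole slices drowns that signal in background. `ctcascade`
implements the classic two-stage answer:

1. **Localize (A1).** An anchor-free grid detector scans each axial slice
   and proposes boxes around tumor candidates; each box is expanded by a
   10-pixel margin and cropped — a *coarse segmentation* that bounds the
   lesion without deciding any pixel. A ground-truth oracle detector is
   provided to isolate the second stage.
2. **Segment (A2).** A shallow U-shaped encoder–decoder (three
   downsamplings, widths 64→128→256→512 at the defaults) whose skip
   connections are replaced by the merged maps of an embedded feature
   pyramid (lateral 1×1 projections, top-down 2× upsampling,
   pixel-by-pixel addition) maps each `(H, W, 3)` crop to `(H, W, 2)`
   class logits. Predicted masks are pasted back at their offsets;
   overlapping crops are unioned.

Training is pixelwise cross-entropy
`L = -Σ p(x_i) log q(x_i)` under small-batch SGD (lr 0.01, momentum 0.9,
weight decay 5e-4, batch 2). Evaluation uses the overlap metrics

```
Dice = 2|Vs ∩ Vg| / (|Vs| + |Vg|)      Jaccard = |Vs ∩ Vg| / |Vs ∪ Vg|
Precision = |Vs ∩ Vg| / |Vs|           Recall  = |Vs ∩ Vg| / |Vg|
```

between predicted (`Vs`) and true (`Vg`) tumor pixel sets, with undefined
cases signalled as `NA` rather than silently mapped to 0 or 1.

Because clinical CT cannot ship with a package, a phantom generator
produces CT-like volumes (ellipsoidal organ, small bright irregular tumor
strictly inside it, Gaussian noise) on which every stage is trainable and
testable end to end. There is no deep-learning framework underneath: the
networks run on a small compiled convolution engine (im2col + GEMM,
hand-derived backward passes, verified against finite differences).

## Worked example

```r
library(ctcascade)

# phantom dataset -> train locator + segnet -> run the cascade on 10
# held-out volumes (~5 min on one CPU)
ex <- run_phantom_experiment(seed = 1)
print(ex$report)
cat("locator slice recall:", ex$locator_recall, "\n")
```

```
<metrics_report> 160 samples, policy = tumor_slices
  dice 0.7344  jaccard 0.6617  precision 0.8993  recall 0.7310
  false-positive slices: 1
locator slice recall: 0.9047619
```

Reading this: over the 160 axial slices of the 10 held-out phantom
volumes, tumor-bearing slices score a mean Dice of 0.73 against ground
truth (a detector miss scores 0 and is *not* excluded); the locator finds
90% of tumor-bearing slices; one tumor-free slice received a spurious
prediction and is counted separately rather than folded into the
averages. The training IoU curve (`iou_of_history(ex$history)`) rises from
0 to a plateau near 0.99 on the evaluation crops.

Lower-level pieces are ordinary functions:

```r
ph  <- generate_phantom(phantom_spec(), seed = 3)
sl  <- extract_slices(ph$volume, ph$labels, window_spec())  # level 40, width 400
s   <- Filter(function(x) x$has_tumor, sl)[[1]]
cr  <- crop_with_margin(s, s$boxes[[1]], margin = 10)
dim(cr$image_crop)   # the A2 input window
```

A thin CLI over the same functions lives at
`inst/cli/ctcascade-cli.R` (subcommands `phantom`, `preprocess`,
`train-locator`, `train-segnet`, `infer`, `evaluate`, `ablate`).

## Package layout

- `R/imaging-io.R` — NIfTI I/O, Hounsfield windowing, slice/box
  extraction, PNG/JPEG export, patient-level splits
- `R/phantom.R` — synthetic volume generator and dataset writer
- `R/locator.R` — focus transform, mosaic augmentation, grid detector,
  oracle detector, margin cropping
- `R/segnet.R` — the shallow U-Net with embedded feature pyramid
- `R/training.R` — cross-entropy, SGD training loop, IoU history
- `R/metrics.R` — Dice/Jaccard/precision/recall and report aggregation
- `R/pipeline.R` — cascade orchestration, end-to-end experiment, ablation
- `src/ops.cpp` — conv/pool/upsample kernels and 8-connected labeling
- `vignettes/cascade-methods.Rmd` — the model, its assumptions, parameter
  defaults, and what phantom results do and do not show
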