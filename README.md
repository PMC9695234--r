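# usseg — liver lesion segmentation for B-mode ultrasound examinations

`usseg` is an R implementation of an end-to-end pipeline for per-pixel
segmentation of focal liver lesions in B-mode ultrasound video. It is aimed
at researchers in medical image analysis who need a complete, reproducible,
dependency-light reference for the classic compact-U-Net + focal-Tversky
recipe: frame sampling and device cropping, polygon-annotation
rasterization, a from-scratch U-Net encoder–decoder (forward and backward
passes implemented against im2col/GEMM kernels in RcppArmadillo — no
deep-learning framework required), class-imbalance-aware metrics, and a
real-time inference timing harness. Because clinical ultrasound data are
rarely shareable, the package ships a synthetic speckle-phantom generator
that produces examinations with exact ground truth, making every stage of
the pipeline testable end to end.

## The method in brief

Frames are sampled from a 7–12 fps examination once per second (frame ids
divisible by `round(fps × Δt)`), cropped to the device's B-mode rectangle,
and paired with binary lesion masks rasterized from expert polygons
(pixel-center even–odd rule, union over polygons). A U-shaped fully
convolutional network — 4 encoder blocks of two 3×3 convolutions + 2×2
max-pooling, a mirrored decoder with nearest-neighbour upsampling and skip
concatenation, and a 1×1 sigmoid head — is trained with minibatch Adam
(α = 1e-4, β₁ = 0.9, β₂ = 0.999, ε = 1e-8) on the focal Tversky loss

    TI  = Σst / (Σst + α·Σs(1−t) + β·Σ(1−s)t),     FTL = (1 − TI)^γ

with two bundled regimes: `"dice"` (α = β = 0.5, γ = 1; TI is then the Dice
coefficient) and `"focal"` (α = 0.7, β = 0.3, γ = 0.75; emphasises
hard-to-segment inputs such as very small lesions). Evaluation reports
IoU = TP/(TP+FP+FN), recall, precision, Dice = 2TP/(2TP+FP+FN) (with the
identity IoU = Dice/(2−Dice)), pixel accuracy, and pixel-level ROC AUC —
with explicit undefined markers for 0/0 cases, because at lesion fractions
of a few percent a high accuracy alone is meaningless.

## Worked example

```r
library(usseg)

# a synthetic examination: one hypoechoic lesion, drifting slowly
les <- lesion_spec(center = c(60, 70), radii = c(18, 12),
                   echogenicity_offset = -70, boundary_roughness = 0.2)
spec <- phantom_spec(width = 128, height = 128, fps = 10, duration_s = 12,
                     lesions = list(les), drift_px_per_s = 1, seed = 42)
ex <- render_examination(spec, "example_exam")
# frames written: 120, per-second ground-truth masks: 12

# ingest: sample at 1 s and crop (identity crop here)
dev <- device_crop_config("phantom", 0, 128, 0, 128, fps = 10)
fs <- extract_frames(ex$frames_dir, dev, sample_time_s = 1)
length(fs$frames)
#> [1] 12

# train the compact U-Net on the default 200-phantom suite
suite <- phantom_suite(n = 200, seed = 11)
ds <- as_dataset(suite, resize_to = 64)
res <- train_unet(ds,
                  unet_config(input_size = 64, base_filters = 8),
                  train_config(epochs = 25, batch_size = 8, seed = 7,
                               resize_to = 64, loss = "dice"))
tail(res$trace[, c("epoch", "train_loss", "train_iou", "val_iou")], 1)
#>    epoch train_loss train_iou  val_iou
#> 25    25 0.09151416 0.8480087 0.805158
```

The final row says: after 25 epochs the running training loss (mean focal
Tversky loss over minibatches) is 0.092, the macro-averaged training IoU is
0.848, and the held-out validation IoU is 0.805 — i.e. on synthetic
phantoms the model overlaps about four fifths of every lesion with its
ground truth on average. Segmenting a new frame and checking the latency
budget:

```r
pred <- unet_predict(res$model, ds$x[[1]] * 255)
sum(pred$mask$pixels) # lesion pixels found
#> [1] 327
ckpt <- save_checkpoint(res$model, "model.ckpt")
benchmark_inference("model.ckpt", ds$x[1:100])
#> inference over 100 frames: min 12.00 / mean 17.16 / max 104.00 ms (load 0.03 s)
#>   real-time (<100 ms/frame): no
```

(The 100 ms flag reflects this particular single-core machine's worst
frame; the mean is well inside one frame period at 7–12 fps. Latency is
hardware-dependent and is reported, never asserted.)

A command-line interface wrapping these functions (subcommands
`extract-frames`, `make-masks`, `gen-phantom`, `model-summary`, `train`,
`predict`, `evaluate`, `benchmark`) is installed at
`system.file("cli", "usseg.R", package = "usseg")`.

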