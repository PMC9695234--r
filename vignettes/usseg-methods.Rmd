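---
title: "Segmenting liver lesions in B-mode ultrasound: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting liver lesions in B-mode ultrasound: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During an abdominal ultrasound examination, the sonographer follows a focal
liver lesion through a live B-mode video while the image drifts with the
patient's breathing and with probe motion. Downstream quantification (for
example, time-intensity curves in contrast-enhanced studies) requires a
stable region of interest around the lesion, which is tedious and
error-prone to maintain by hand. `usseg` implements a complete pipeline for
learning and applying an automatic per-pixel lesion segmentation on such
examinations:

1. **ingest** — sample frames from an examination at a fixed time interval
   and crop them to the device's B-mode rectangle;
2. **annotation** — turn expert polygon outlines into full-frame binary
   masks;
3. **phantom** — generate synthetic speckle-textured examinations with
   exact ground truth, so the whole pipeline is testable without clinical
   data;
4. **model** — a compact U-Net encoder–decoder;
5. **losses** — the focal Tversky loss family;
6. **metrics** — class-imbalance-aware evaluation;
7. **pipeline** — dataset assembly, splitting, Adam training, and a
   real-time inference harness.

## Frame extraction and cropping

Handheld B-mode examinations run at 7–12 frames per second, and consecutive
frames are nearly identical; annotating all of them would label the same
image many times. The ingest stage therefore keeps one frame per sampling
interval: with stride $k = \mathrm{round}(fps \cdot \Delta t)$ (default
$\Delta t = 1$ s), exactly the frames whose 0-based index is a multiple of
$k$ are retained, giving $\lfloor (N-1)/k \rfloor + 1$ frames from an
$N$-frame video. Each kept frame is cropped to the device-specific B-mode
rectangle, specified as half-open 0-based pixel ranges so that the
coordinate row (0, 400, 78, 525) of the bundled example device yields a
400 × 447 crop. Which raster axis "x" refers to differs between vendors, so
it is an explicit configuration field (`axis_order`) rather than an
assumption. Video containers are consumed as lossless PNG frame
directories (or in-memory frame lists); colour frames are reduced to
luminance before cropping.

## From polygons to masks

Expert annotations arrive as GeoJSON polygons drawn on the cropped frame.
A pixel belongs to the lesion mask iff its center — pixel $(c_x, c_y)$ has
center $(c_x + 0.5, c_y + 0.5)$ — lies inside or on the boundary of at
least one polygon, by the even–odd rule; multiple polygons (and
MultiPolygon parts) combine by union. Union (rather than intersection)
combination is deliberate: an intersection with a zero-initialized canvas
would always be empty, and multi-lesion frames must show several foreground
regions. The rule is deterministic and is verified bit-exactly in the test
suite against a brute-force per-pixel point-in-polygon oracle and against
an independent implementation (`mgcv::in.out`). Masks are stored as 8-bit
PNGs with foreground 255, named `<frame base>-mask.png`, and round-trip
exactly.

## The synthetic phantom

No public dataset accompanies this problem, so the package generates its
own study material. A phantom frame is

$$I = \mathrm{clip}\big((b + \textstyle\sum_j o_j\, s_j)\, T,\ 0,\ 255\big)$$

where $b$ is the parenchyma level, $s_j$ the (optionally edge-blurred)
support of lesion $j$, $o_j$ its signed echogenicity offset (negative =
hypoechoic, the typical appearance of focal liver lesions; positive =
hyperechoic), and $T$ a multiplicative speckle texture: a Rayleigh field
smoothed with a small box kernel and normalised to unit mean, with its
deviation scaled by `speckle_scale`. This is a first-order imitation of
ultrasound speckle — multiplicative, spatially correlated, Rayleigh-like —
not a wave-propagation simulation. Lesion supports are ellipses with an
optional low-order harmonic boundary perturbation; the ground-truth mask is
the *pre-blur* union of supports, because expert polygon labels are crisp
even when the image boundary is soft. Slow translation (`drift_px_per_s`)
emulates breathing/probe drift across a multi-second examination.
Rendering is bit-deterministic in (spec, seed, frame index).

The default suite (`phantom_suite(n = 200)`) fixes the study conditions
used by the convergence tests: frames rendered at 128 × 128; 70 % single
lesions with area fraction 2–20 % of the frame, 15 % dedicated small-lesion
cases (0.5–2 %), 15 % two-lesion phantoms (including adjacent pairs); 20 %
of lesions hyperechoic; `speckle_scale` 0.25; background level uniform in
100–140. These proportions were chosen once as a plausible desk-scale
imitation of a clinical mix dominated by moderate-size hypoechoic lesions
with a meaningful minority of small and multiple lesions.

**What passing tests do and do not show.** The phantoms share the
first-order statistics of B-mode data (grayscale, speckle, hypo/hyper
contrast, small foreground fractions, inter-frame drift) but none of its
anatomy: no organ boundaries, vessels, shadowing, attenuation, or
depth-dependent focus. Convergence on phantoms demonstrates that the
optimisation, loss, and architecture are implemented correctly — it says
nothing about clinical performance.

## The compact U-Net

The model is a U-shaped fully convolutional network: 4 encoder blocks of
two 3 × 3 convolutions (ReLU) each followed by 2 × 2/stride-2 max pooling,
a bottleneck block, and a mirrored decoder that 2× nearest-neighbour
upsamples, concatenates the matching encoder output (skip connection), and
applies two more convolutions; a 1 × 1 convolution + sigmoid head emits the
per-pixel lesion probability. Filters start at `base_filters` and double at
each pooling level.

Numerical and design choices that were genuinely open:

* **Padding.** `same` zero padding is the default: the labels are
  full-frame masks, so the output must keep the input extent. An unpadded
  (`valid`) mode is retained for fidelity experiments — it is realised by
  trimming the border of the padded convolution (value-identical to a true
  unpadded convolution) and only admits input sizes whose intermediate
  extents stay even at every pooling step.
* **Width.** `base_filters` is configurable (default 16; the desk-scale
  studies use 8). The closed-form parameter count
  $\sum_\ell (k^2 c_{in} + 1) c_{out}$ is exposed
  (`unet_parameter_count()`) and checked against the stored arrays, so any
  width choice is auditable.
* **Head and threshold.** A 1 × 1 convolution + sigmoid head and a 0.5
  binarisation threshold are the conventional binary-segmentation choices.
* **Initialisation.** He-normal weights with zero biases; the head uses
  Glorot scaling. Inputs are zero-centered inside the forward pass (datasets
  keep the plain [0, 1] intensity convention), which materially accelerates
  early optimisation within a short training budget. A negative
  "background-prior" head bias — a common trick for class-imbalanced dense
  prediction — was evaluated and rejected: with the fixed small learning
  rate it can trap some initialisations below the 0.5 decision threshold
  for the entire training budget.
* **Implementation.** Forward and backward passes are written against
  im2col + GEMM convolution kernels (RcppArmadillo), with max-pool argmax
  routing and nearest-neighbour upsampling gradients; the whole
  backpropagation is validated against central finite differences layer by
  layer (median relative error ~1e-7).

## The loss family

For a predicted probability map $s$ and binary reference $t$, the soft
Tversky index is

$$TI = \frac{\sum s t + \epsilon}{\sum s t + \alpha \sum s(1-t) +
\beta \sum (1-s)t + \epsilon}$$

and the focal Tversky loss is $FTL = (1 - TI)^\gamma$. $\alpha$ weights
false positives, $\beta$ false negatives; $\alpha = \beta = 0.5$ makes $TI$
the Dice coefficient and $\alpha = \beta = 1$ the Jaccard index — both
identities are asserted to 1e-9 in the tests (against the *unsmoothed*
index; the smoothing $\epsilon = 10^{-6}$, default in training, exists so
that an empty reference with an empty prediction scores 1 rather than
0/0). Two presets are bundled: `"dice"` (0.5, 0.5, 1), which treats all
labels equally, and `"focal"` (0.7, 0.3, 0.75), which focuses training on
hard-to-segment inputs such as very small lesions. The loss is computed
per image and averaged over the batch — per-image aggregation is what
makes a small lesion matter within its own frame; a pooled-batch variant
would let large lesions dominate. Probabilities are clamped to
$[10^{-7}, 1-10^{-7}]$ before logarithms in the cross-entropy losses, and
the printed binary cross entropy is the standard
$-(y \log p + (1-y)\log(1-p))$.

## Metrics under class imbalance

A lesion often occupies a few percent of the frame, so pixel accuracy is
uninformative: an all-background predictor on a 10 % lesion scores
accuracy 0.90 with IoU and recall 0 (this scenario is asserted exactly in
the tests). The metrics module computes IoU, recall, precision, Dice and
accuracy from per-frame confusion counts, plus pixel-level ROC AUC
(trapezoidal, tie-aware, equal to the Mann–Whitney statistic). Zero
denominators propagate as an explicit undefined marker (`NA`) and are
excluded from macro averages with the exclusion count reported — silently
scoring an empty-vs-empty frame as 0 would bias per-frame averages
downward. Dataset-level reporting is macro (per-frame average) by default,
with a pooled-counts micro option.

## Training protocol

The dataset is split 70/20/10 into training/validation/test. The default
split unit is the *examination* (all frames of one examination stay
together), because frames sampled one second apart from the same video are
near-duplicates and a frame-level split would leak them across partitions;
the frame-level mode remains available and follows the floor-validation,
floor-test, remainder-to-train rounding rule (6035 frames → 4225/1207/603).
Training runs 25 epochs of minibatch Adam (learning rate 1e-4,
$\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$) with batch size
8. One global seed drives split, initialisation and shuffling, so runs are
bit-reproducible. Per-epoch training metrics are running averages over the
minibatches (predictions taken before each update, the convention of the
common deep-learning frameworks); validation metrics are computed after
each epoch on thresholded (0.5) masks. The best-validation-IoU weights are
retained alongside the final ones, IoU being the headline segmentation
metric. Divergence (non-finite loss) aborts with the trace so far.

### Problem sizes

The bundled studies run at deliberately compact scale, chosen as this
package's own desk-scale conditions: 200 phantoms rendered at 128 × 128
and resized (bilinear for frames, nearest-neighbour for masks, aspect
ratio not preserved) to a 64 × 64 model input, `base_filters = 8`
(≈ 120 k parameters). Under these conditions the 25-epoch dice-preset run
reaches training IoU ≈ 0.85 and validation IoU ≈ 0.8; the focal preset is
exercised on a small-lesion-dominated suite where its recall is checked to
stay competitive with the dice preset's. Larger inputs (the conventional
256 × 256) and wider models are configuration changes, not code changes.

## Inference and timing

`unet_predict()` performs exactly one forward pass per frame — the
property that makes a U-Net viable for real-time use, since one frame
period at 7–12 fps is 83–143 ms. `benchmark_inference()` wall-clocks the
per-frame prediction over a set of frames (model loading is timed once,
separately, as it happens once at system start-up) and reports min/mean/max
milliseconds plus a flag for the 100 ms budget; the flag is informative,
not asserted, because latency is hardware-dependent.

## Known limitations

* The phantom is a first-order texture model; see the caveats above.
* Only binary (lesion vs background) segmentation is supported; no
  object-level detection metrics.
* No DICOM or compressed-video ingestion; examinations are consumed as
  PNG frame directories.
* The `valid` padding mode restricts admissible input sizes and is
  forward-only (training uses `same`).
* AUC is computed at pixel level; aggregating ranking quality across
  frames of very different lesion sizes is left to the caller.
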