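---
title: "sproutnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sproutnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sproutnet)
```

## The problem

Scoring pea germination on incubator plates is a counting task: every seed
on every daily image must be located and classified as *sprout* or
*not_sprout*, where a seed counts as germinated once its germ reaches half
the seed's own length. From those per-day counts two vigor statistics are
derived — the **germination rate** $100\,N_t/N$ (cumulative percentage
germinated by day $t$ out of $N$ seeds sown) and the **germination index**
$\sum_t G_t/D_t$ (newly germinated seeds $G_t$ on day $D_t$, weighting early
germination more) — which in turn support screening genotypes for drought
tolerance (control vs. PEG6000-stress conditions).

`sproutnet` implements the detector family designed for this task —
YOLOv8-Peas, a lightweight derivative of the YOLOv8-n anchor-free
detector — together with everything around it: analytic complexity
accounting, label-preserving augmentation, annotation I/O, a synthetic
plate generator, detection metrics, the Adam optimizer, a desk-scale smoke
trainer, and the vigor statistics.

## The architecture and its lightweight blocks

The baseline is the standard -n scale detector: a CBS stem
(convolution + batch norm + SiLU), four downsampling stages with C2f
split-transform-merge blocks, SPPF, a PAN-FPN neck, and a decoupled
anchor-free head predicting, per feature-map cell, a discrete distribution
over `reg_max = 16` bins for each of the four box-side distances
(distribution-focal representation) plus per-class logits. At width 0.25 /
depth 0.33 with two classes this counts 3,011,222 learnable scalars
(3.011 M).

Four substitutions make the light model:

* **C2f-Ghost** — every two-convolution bottleneck becomes a
  `ghost_bottleneck()`: two stacked ghost convolutions on `c` channels (the
  second without activation) with a residual connection. A
  `ghost_conv()` produces half its output with a primary 1×1 convolution
  and the other half with a cheap linear transform of that primary output.
* **DBS** — selected stride-2 downsampling convolutions become grouped
  convolutions with `gcd(c_in, c_out)` groups, dividing their weight count
  and FLOPs by the group count.
* **PDetect** — both stacked 3×3 convolutions of each head branch are
  replaced by `pcc()` partial-convolution blocks: a 3×3 convolution on a
  $1/r$ channel slice ($r = 4$) spliced back and fused by a 1×1
  convolution. Relative FLOPs follow $1/r^2 + 1/k^2$ (`pconv_ratio()`),
  25/144 at $k=3, r=4$.
* **CARAFE** — both neck upsamples become content-aware: a 1×1 compressor
  to 64 channels, a $k_{enc}\times k_{enc}$ encoder to
  $\sigma^2 k_{up}^2$ channels, pixel-shuffle, per-position softmax
  normalization, and reassembly of each output value from the
  $k_{up}\times k_{up}$ source neighborhood. Defaults $k_{up}=3$,
  $k_{enc}=5$, $\sigma=2$.
* **Coordinate attention** after the first C2f-Ghost stage: axis-wise
  pooling, a shared 1×1 reduction to `max(8, c/32)` channels with
  h-swish, and two sigmoid-gated 1×1 expansions that re-weight the input.

```{r params, eval = FALSE}
count_params(build_model(yolov8n_config()))     # 3,011,222
count_params(build_model(yolov8_peas_config())) # 1,176,374
```

## Calibration of under-specified details

The published description leaves several block-level details open; the
printed parameter table of the ablation study pins them down to integer
precision, and `scripts/calibrate.R` documents the search:

* **Ghost cheap transform.** A depthwise 5×5 cheap transform (the GhostNet
  convention) or a half-width `c → c/2 → c` bottleneck counts 2.10–2.14 M
  for the C2f-Ghost model — but the printed value is 2.145 M, and jointly
  with the 1.580 M DBS row it determines the ghost bottleneck exactly:
  $1.5c^2 + 4c$ parameters, i.e. two full-width `GhostConv(c → c)` units
  whose cheap transform is a dense (pointwise) 1×1 convolution on the
  primary half. That structure is the frozen default
  (`ghost_cheap_kernel = 1`, dense); the depthwise variant stays available
  in the configuration.
* **DBS placement.** Enumerating all $2^7$ subsets of the stride-2
  convolutions leaves exactly one subset (up to the stem, where
  `gcd(3,16) = 1` makes DBS a no-op; the tie is broken toward fewer
  replacements) that reproduces 1.580 M: all backbone downsamples from P3
  on plus both neck downsamples, and *not* the 16→32 P2 downsample.
* **CARAFE compressor width.** The parameter deltas between the seven
  published kernel-size variants are linear in the compressor width with
  slope $2(k_{enc}^2\sigma^2k_{up}^2)$ differences; they are consistent
  only with $C_m = 64$, which also reproduces all seven table entries
  under two-decimal truncation (1.06 … 2.29 M).
* **CA placement and reduction.** At the stated placement (after the first
  C2f-Ghost, 32 channels) with the conventional `mid = max(8, c/32)`, the
  attention block adds 856 parameters and the full model lands on
  1,176,374 → 1.176 M, matching the final printed row and the truncated
  headline 1.17 M.

Two intermediate rows of the printed ablation table (1.710 and 1.171 M)
cannot be reconstructed from any structure consistent with the other six
printed values; they are treated as printing anomalies, and the package
reproduces the final model and both headline variants exactly.

## FLOP accounting

`count_flops()` charges each convolution
$2\,H_{out}W_{out}\,(C_{in}K^2/g + 1)\,C_{out}$ at its own output
resolution, and (by default) unfused batch norm at 2 ops/element,
activations at 1 op/element, max-pooling at $k^2$/element, upsampling,
residual additions and attention gating at 1 op/element, and the CARAFE
reassembly dot products. Under this convention the 2-class baseline counts
8.2 GFLOPs at 640×640. The same convention yields 3.0 GFLOPs for the full
model, one rounding notch under the published 3.2 G: because parameters pin
the architecture exactly and FLOPs of stride-1 blocks are proportional to
their parameters at fixed resolution, no per-pixel counting convention can
reproduce both the baseline's 8.2 G and the derived models' FLOPs column;
the discrepancy is reported rather than absorbed into the convention.

## Augmentation

`transform_image()`/`transform_labels()` implement five label-preserving
methods (multiplicative brightness, horizontal/vertical flip, whole-image
scaling, additive Gaussian noise) with the exact coordinate maps — flips
mirror corners, scaling multiplies all coordinates by $s$, photometric
methods leave geometry untouched. Pixel noise cannot move true geometry,
so the noise method keeps labels fixed by default; an optional
`jitter_sigma` perturbs coordinates for robustness experiments.
Coordinates are 0-based half-open corners; conversions to normalized
center format round-trip within 1 px. `augment_dataset()` emits exactly
one augmented copy per original (doubling, e.g. 1017 → 2034) with a
deterministic per-image method draw and a manifest. Parameter ranges
(gain 0.6–1.4, scale 0.7–1.3, noise σ = 10 on a 0–255 scale) are
conventional choices, not published values. Boxes pushed outside the frame
by scaling are clipped, and boxes that collapse are dropped with a logged
warning.

## The synthetic generator

`generate_plate_series()` emulates the acquisition setup at desk scale:
a grid of speckled ellipses (default 6×6 — the 36-seed plate layout) on a
textured background, germs drawn as quadratic Bézier strokes anchored at
the seed edge, root-like clutter curves crossing the plate, and per-day
global brightness jitter. Germination days are drawn from a per-day hazard
(default 0, 0.4, 0.35, 0.3, 0.2 — germination starting on day 2 and
reaching roughly 80 % by day 5, the control-condition behavior); a germ
appears as a sub-criterion nub the day before and crosses the
half-seed-length criterion exactly on the drawn day, so the class flip day
is exact by construction. The generator returns pixel-exact boxes, per-day
labels, the event table and the seed layout, and is the ground-truth
source for the vigor parameter-recovery tests. It is deliberately
synthetic: passing tests demonstrate pipeline correctness on controlled
imagery, not detection performance on real plates (no specular water,
condensation, seed coats, or touching root mats).

## Training at desk scale

`smoke_train()` verifies that the whole loop learns without pretending to
be a full training run. The backbone, neck and branch trunks stay frozen
at their random initialization; the trainable slice is the last two layers
of each head branch (the 1×1 fuse convolution of the second PCC block and
the final prediction convolution). Because the frozen batch-norm layers
have no trained statistics, features are extracted under training-mode
(per-map) normalization, and the backward pass through that normalization
and SiLU is exact (verified against finite differences in the test suite).
The loss is the standard anchor-free composite — binary cross-entropy on
class logits (with an up-weighted positive term, the positives being a few
seed cells against hundreds of background anchors), complete-IoU on the
decoded boxes, and distribution-focal loss on the box-side bins, weighted
7.5/0.5/1.5 — optimized by `adam_step()` (β₁ = 0.937, β₂ = 0.999, learning
rate 10⁻² decaying linearly to 10⁻⁴, weight decay 10⁻⁴, batch 8). Targets
use a center-region assigner at a size-matched level. On a 200-image easy
synthetic set (2×2 grids, no clutter) with 30 epochs this runs in a couple
of minutes on one CPU core and reliably lifts validation mAP@0.5 above the
untrained model (typically to roughly 0.1); the test suite uses a
scaled-down 50/20-image version of the same check. Linear-probe training
of a frozen random backbone cannot approach deployment accuracy, and is
not meant to.

## Evaluation and numerical choices

* **AP** uses all-point (continuous) interpolation of the precision
  envelope; mAP@0.5 is the unweighted class mean. `0/0` precision or
  recall is defined as 0 (empty early-training prediction sets), with a
  logged note.
* **Matching** is greedy, confidence-descending, one-to-one within class;
  **NMS** is class-wise greedy at IoU 0.65.
* **Decoding** takes the expectation over the softmaxed distance bins;
  anchors sit at cell centers, `(i + 0.5) * stride`.
* Batch-norm ε is 10⁻³; softmax is computed with max-subtraction;
  weight initialization is Kaiming-uniform under the configuration seed,
  making builds bit-reproducible.
* Degenerate inputs fail loudly: non-divisible-by-32 images, even CARAFE
  kernels, split ratios not dividing the channel count, malformed
  annotation files (with line/element named).

## Vigor analysis

`series_from_detections()` assigns detections to the nearest layout cell
by box centroid (seeds do not move in the incubator), takes a seed's
germination day as the first day a `sprout` detection lands on its cell,
and enforces monotonicity (later `not_sprout` detections are logged as
detector noise). On noiseless synthetic detections the recovered $N_t$,
$G_t$ and per-seed event days equal the generator's table exactly.
`compare_conditions()` averages replicate plates per genotype and
condition before computing final-day rate, index, and the percent decrease
$100\,(CK - S)/CK$, pooled and per genotype; day indexing is 1-based from
the first scored day.

## Known limitations

* The smoke trainer adapts only the head's last two layers; detection
  quality on real imagery requires full training in a deep-learning
  framework.
* FLOP totals depend on the stated convention; the published FLOPs column
  is internally inconsistent with the published parameter column (see
  above) and is matched only for the baseline.
* The generator's appearance model is intentionally simple; it bounds what
  green tests can claim about field imagery.
* Forward passes are pure R (BLAS-backed im2col); they are meant for
  desk-scale verification, roughly 0.1–0.4 s per 96×96 image, not for
  deployment.
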