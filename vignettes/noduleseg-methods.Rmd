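---
title: "Methods: lung-nodule segmentation with multi-scale UNets and an attention FPN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lung-nodule segmentation with multi-scale UNets and an attention FPN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`noduleseg`, the choices that were genuinely open when building them, and
what the synthetic-phantom experiments do and do not demonstrate.

## The problem

Pulmonary nodules are approximately spherical lesions inside the lung
parenchyma. On a CT slice they appear as small bright blobs inside the dark
lung fields, frequently low-contrast against vessels and airway walls.
Semantic segmentation labels every pixel as nodule / not-nodule; overlap
metrics (Dice similarity coefficient and intersection-over-union) measure
agreement with reader-drawn reference contours.

## Preprocessing chain

`preprocess_slice()` applies, in order:

1. **HU clamp** to [-1000, 400] — applied only when the slice is
   Hounsfield-calibrated (minimum below -500). Air is approximately
   -1000 HU and bone starts above +400 HU; clamping removes out-of-body
   extremes before normalization. Grayscale inputs are left untouched.
2. **Standardization** to zero mean and unit *population* variance.
   Constant slices are rejected (degenerate input) rather than silently
   returning zeros.
3. **Median filter**, default 3×3, reflection padding. Odd windows only;
   window 1 is the identity.
4. **Perona–Malik anisotropic diffusion**: explicit 4-neighbour updates
   `x += γ Σ c(|∇x|) ∇x` with conduction `exp(-(g/κ)²)` (default) or
   `1/(1+(g/κ)²)`. Defaults: 10 iterations, κ = 30, γ = 0.1. γ is
   restricted to (0, 0.25], the stability bound of the explicit scheme;
   boundaries are zero-flux, so constant images are exact fixed points and
   the variance of the image never increases.
5. **K-means thresholding** of the intensity histogram (k = 2 by default,
   `stats::kmeans` with 10 restarts under a fixed seed). The "inter-cluster
   threshold" is taken at the midpoint of the largest gap between sorted
   cluster centers; clusters whose center falls below it are labeled 1.
   On CT this captures air and lung parenchyma. The rule is deterministic
   under the seed and invariant to cluster relabeling.
6. **Morphological opening** (erosion then dilation, disk of radius 2) on
   the binary candidate mask. Outside-image pixels count as background, so
   opening is anti-extensive and idempotent exactly.
7. **Lung-region selection**: 8-connected components are labeled;
   components touching the border strip (width 2 px — the surrounding air
   reaches the image edge, the lungs do not) or smaller than 0.5 % of the
   image area are dropped; the two largest survivors are the lung fields.
   Interior holes are then filled: bright structures (nodules, vessels)
   punch holes into the low-intensity candidate mask, but they belong to
   the lung field, and a lung mask that excluded every nodule would defeat
   the purpose of the ROI. Hole filling is the package's addition to the
   minimal component rule; it is standard practice in lung masking and is
   controlled by `fill_holes`.
8. **ROI extraction**: the lung mask is dilated (disk of radius 5, a safety
   margin for juxtapleural structures) and multiplied with the original
   slice. The *returned* `lung_mask` is the selected-regions mask before
   this margin dilation; the dilation only widens the ROI.

Reader annotations are rasterized per reader (closed polygons, scanline
fill plus the drawn outline so boundary pixels are included), filtered by
equivalent diameter (circle of equal area × pixel spacing; nodules under
3 mm are kept in the parsed set but excluded from masks by default), and
merged by per-pixel majority: a pixel is a nodule pixel when at least half
of the readers marked it. The merge fraction is configurable; 50 % is a
neutral default between union and unanimity.

## Network blocks

All feature maps are `(height, width, channels, batch)` arrays — the
column-major layout natural to R image packages. Convolutions before batch
normalization carry no bias (the BN shift makes it redundant and
gradient-free).

* **Multi-scale block**: parallel 3×3 and 7×7 same-padded convolutions
  (each conv → BN → activation), concatenated and fused by a 1×1
  convolution. The fusion is concatenate-then-1×1 so both receptive fields
  survive with a controlled channel count.
* **Asymmetric convolution block (ACB)**: the sum of 3×3, 1×3 and 3×1
  branches, then one batch normalization and activation. Because the three
  branches are linear, the training-time forward uses the single fused 3×3
  kernel (3×3 kernel + 1×3 padded into the middle row + 3×1 padded into the
  middle column); the branch-kernel gradients are slices of the fused
  gradient, so this is an exact reformulation, and the explicit
  three-branch path (`branch_sum`) is kept and tested against it.
* **Channel attention block (ChAB)**: 1×1 reduction, global average and max
  pooling, a shared two-layer bottleneck (squeeze to 1/16 of the channels,
  restore), sum, sigmoid, channel-wise rescaling. Sharing the bottleneck
  between the two pooling branches follows CBAM, the block's basis. The
  per-branch alternative was tried first and rejected: with hard-zero
  activations (ReLU) the narrow avg-branch bottleneck (as few as 2 units at
  the finest level) can be dead at initialization for every input, leaving
  parameters that never receive gradient; the shared bottleneck always sees
  the max-pooled vector as well and keeps every parameter trainable.

Activations are registry-based (`SELU`, `ELU`, `GELU`, `Mish`, `Swish`,
`ReLU`, `LeakyReLU`). GELU defaults to the exact Gaussian-CDF form
`0.5·x·(1 + erf(x/√2))` with the tanh approximation (cubic constant
0.044715) available as a variant; the two agree within 5·10⁻³ on [-5, 5].
GELU is the package default throughout: its smooth probabilistic gating
retains the small negative responses that matter for low-contrast nodule
boundaries and avoids dead units.

## Architectures

* **`msunet`** — encoder of multi-scale blocks with 2× max pooling,
  a multi-scale bottleneck, and a decoder of 2×2-stride transposed
  convolutions with concatenated skip connections, multi-scale blocks, and
  a 1×1 + sigmoid head. Default widths are (16, 32, 64, 128) with a
  256-channel bottleneck. The widths are the package's own choice — no
  reference widths exist for this architecture — and are deliberately
  light so that the reference configuration trains in minutes on a single
  CPU core; they are configurable (`widths`) for larger studies.
* **`acb_unet`** — five encoder levels of ACBs, widths
  (32, 64, 128, 256, 512). The deepest decoder map equals the deepest
  encoder map. Each shallower decoder level j fuses two branches: (A) the
  same-level encoder map plus all shallower encoder maps max-pooled to
  level-j resolution (1×1-projected to the level width so the sum is
  well-typed), passed through an ACB; and (B) all deeper decoder maps
  brought to level-j resolution by chains of 2× transposed convolutions,
  summed and passed through an ACB. [A, B] is concatenated and a ChAB
  (reduction = level width, so 128 filters and a squeeze of 8 at level 3)
  emits the decoder map. ACBs after the transposed convolutions suppress
  the checkerboard artifact that plain deconvolution decoders produce.
* **`fpn_la`** — a ResNet-34 backbone (stem 7×7/2 + 2× pool; stages of
  3/4/6/3 basic blocks at widths 64/128/256/512) emits F2–F5 at 1/4 … 1/32
  of the input; F1 is never kept. The top-down pathway applies a 1×1
  lateral convolution per level, adds the 2× nearest-neighbour-upsampled
  coarser map, and smooths each merged map with a 3×3 convolution
  (applied to M5 as well, so P5 exists for aggregation). Laterals sit
  before the addition — the standard FPN dataflow. With pyramid width
  d = 64 the concatenated P2–P5 embedding has 256 channels; a 1×1 fusion,
  single-head linear attention (QKV from 1×1 convolutions, embedding 256)
  and a residual addition of the original concatenation form the attention
  aggregation module. The head is a 3×3 convolution, 4× bilinear upsampling
  to input size (nearest would alias the 4× jump), a 1×1 convolution and a
  sigmoid. The backbone is always trained from scratch; no downloaded
  weights are involved.

## Linear attention

With `M` flattened spatial positions, queries/keys/values `Q, K, V` and
L2-normalized rows `q̂, k̂` (a 10⁻⁶ stabilizer is added to the norms), the
output row is

\[
\mathrm{Att}(Q,K,V)_x =
\frac{\sum_y v_y + \hat q_x^\top \left(\sum_y \hat k_y v_y^\top\right)}
     {M + \hat q_x^\top \sum_y \hat k_y}.
\]

This is the first-order Taylor approximation `exp(q̂ᵀk̂) ≈ 1 + q̂ᵀk̂` of
softmax attention; normalization guarantees `q̂ᵀk̂ ≥ -1`, so the implicit
weights are non-negative and sum to one. The two bracketed summaries are
computed once and reused for every query: O(M) time and memory, and no
M×M array is ever materialized. The denominator carries no additional
stabilizer — that keeps the single-position case exactly `v₁` and the
weight normalization exact — and the adversarial case of a vanishing
denominator (every key antipodal to a query) raises an error instead of
being silently damped. `softmax_attention()` (max-shifted, O(M²)) is the
reference implementation the linear form is tested against.

## Training and evaluation

The loss is `w₁·BCE + w₂·DiceLoss` with `w₁ = w₂ = 0.5` and Dice smoothing
`s = 1`; sigmoid probability maps are clipped to [10⁻⁷, 1 − 10⁻⁷] (so
saturated logits still yield probabilities strictly inside the unit
interval and finite log-likelihoods).
The optimizer is Adam (β₁ = 0.9, β₂ = 0.999) with learning rate 10⁻⁵ and
L2 weight decay 10⁻⁴ folded into the gradient; defaults are batch 8 and
200 epochs, with 80/10/10 train/validation/test splits (largest-remainder
rounding, seeded shuffle). Phantom splits are at sample level; for real
data, splitting should be at patient level to avoid slice leakage.
Training retains the parameter state with the best validation DSC when a
validation set is supplied. Evaluation binarizes probabilities at τ = 0.5
and averages per-image metrics (an unweighted mean over images; pooled-
pixel aggregation can be recovered from the reported confusion counts).
Degenerate ratios take the agreement convention — an empty prediction of an
empty reference is perfect (DSC = IoU = 1) — and are flagged.

## Numerical core

A compact reverse-mode autodiff engine (environment-based tensors with
topological-order backward) drives training. Convolutions are evaluated in
C++ via one GEMM per kernel offset over batch-stacked feature matrices
(stride-2 convolutions fall back to im2col); stride-1 GEMMs run in single
precision, the standard arithmetic for CNN training, while everything
outside the networks (attention functions, metrics, preprocessing) is in
double precision. Batch normalization uses ε = 10⁻⁵ and momentum 0.1;
transposed convolutions use 2×2 kernels with stride 2 (exact doubling, no
output-padding ambiguity); weights are He-initialized under the model's
seed, so builds are bit-reproducible.

## Synthetic phantoms

`generate_phantom()` draws a bright body ellipse containing two dark,
vertically elongated lung ellipses and 0–5 brighter elliptical nodules
placed strictly inside the lung fields (disjoint by default so the
8-connected component count equals the nodule count; a `juxtapleural` flag
allows boundary-touching nodules for hard cases). Intensities emulate a
soft-tissue-windowed slice on a 0–1 scale — background 0.02, lung 0.18,
nodule 0.65, body 0.70 — with additive Gaussian noise (σ = 0.04). The
ordering background < lung < nodule ≤ body is what makes the K-means lung
step and the segmentation task non-trivial: nodules are holes in the dark
lung candidate mask and low-contrast against the body.

The phantoms exercise every stage — filtering, clustering, morphology,
region selection, training, metrics — with exact ground truth and no
downloads. They do **not** reproduce real CT texture, reconstruction
kernels, vessels, fissures, ground-glass opacity or reader disagreement, so
passing phantom experiments demonstrates that the implementation is
correct and trainable, not that the reported clinical-scale accuracies
transfer; results on real cohorts require the full-resolution data and
long training schedules outside this package's test envelope.

Reference experiment sizes used by the test-suite and the acceptance
script — chosen as the package's reference desk-scale configuration — are
128 phantoms at 64×64 px, batch 8, 15 epochs for the three-architecture
training check (the acceptance script uses 64 phantoms and 8 epochs for
its single-architecture run), 20 seeded phantoms at 128×128 px for the
lung-segmentation IoU, and 20 seeded random instances for each algebraic
equivalence check.

## Known limitations

* 2D slices only; no 3D context, vessel removal or fissure analysis.
* The LIDC-style XML parser is best-effort (reading sessions, edge maps,
  z-position-ranked slices); the simplified JSON dialect is the reference
  annotation format.
* DICOM support covers uncompressed little-endian transfer syntaxes with
  standard rescale tags.
* Single-head attention only; no stacked transformer layers, no multi-head
  variant, by design.
* CPU-only: practical for the phantom scale and for inference; full-scale
  training on clinical datasets is out of scope.
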