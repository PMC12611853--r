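# noduleseg

Semantic segmentation of pulmonary nodules on 2D CT slices, in R.

Lung nodules are small (often < 10 mm), low-contrast structures embedded in
a bright thorax; finding every nodule pixel is the first step of computer-
aided lung-cancer screening. `noduleseg` provides the full desk-scale
pipeline:

* **CT preprocessing** — intensity standardization, median filtering,
  Perona–Malik anisotropic diffusion, K-means intensity thresholding,
  morphological opening, connected-component lung-field selection and ROI
  extraction; plus rasterization of multi-reader nodule contour annotations
  into consensus masks (with the customary ≥ 3 mm nodule-size rule).
* **Three trainable encoder–decoder networks**
  * `msunet` — a multi-scale UNet whose encoder/decoder blocks run parallel
    3×3 and 7×7 convolutions, concatenated and fused 1×1;
  * `acb_unet` — a UNet with asymmetric convolution blocks
    (3×3 + 1×3 + 3×1 branches, batch-normalized), multi-scale skip
    connections (max-pooled shallower encoder maps and transposed-conv
    upsampled deeper decoder maps summed, ACB-processed, concatenated) and
    channel attention (CBAM-style avg/max squeeze–excite with a 1/16
    bottleneck);
  * `fpn_la` — a ResNet-34 feature pyramid network whose P2–P5 maps
    (64 channels each) are concatenated into a 256-channel embedding and
    refined by single-head **linear attention**, then decoded by a small
    segmentation head.
* **Linear attention** — softmax attention with the first-order Taylor
  approximation `exp(qᵀk) ≈ 1 + qᵀk` on L2-normalized queries and keys:

  ```
  Att(Q,K,V)ₓ = [ Σ_y v_y + q̂ₓᵀ Σ_y k̂_y v_yᵀ ] / [ M + q̂ₓᵀ Σ_y k̂_y ]
  ```

  The two key summaries are computed once and reused for every query, so
  attention over M spatial positions costs O(M) time and memory instead of
  O(M²); `softmax_attention()` is retained as the quadratic reference.
* **Training and evaluation** — the BCE-Dice objective
  `L = w₁·BCE + w₂·(1 − (2Σpt + s)/(Σp + Σt + s))`, Adam with weight decay,
  seeded 80/10/10 splits, and overlap metrics (precision, recall, accuracy,
  DSC = 2|G∩P|/(|G|+|P|), IoU = |G∩P|/|G∪P|).
* **Synthetic thorax phantoms** — reproducible grayscale slices with two
  lung fields and 0–5 bright elliptical nodules plus paired masks, so the
  entire pipeline is testable without any external imaging data.

The networks run on a compact reverse-mode automatic-differentiation core
built into the package, with C++ (RcppArmadillo) convolution, pooling and
resampling kernels — no external deep-learning framework is required.

## Worked example

```r
library(noduleseg)

# 1. a reproducible thorax phantom and its lung segmentation
ph <- generate_phantom(phantom_config(seed = 3))
ph
#> <phantom_sample> 128 x 128 | 4 nodule(s) | lung area 4636 px
res <- preprocess_slice(ph$image)
sum(res$lung_mask & ph$lung_mask) / sum(res$lung_mask | ph$lung_mask)
#> [1] 0.9592321

# 2. train the attention FPN on 64 small phantoms for a few epochs
ds  <- generate_phantom_dataset(48, phantom_config(image_size = 64, seed = 101))
mod <- build_model(model_config("fpn_la", seed = 5))
mod
#> <nodseg_model> fpn_la | activation: GELU | parameters: 21,897,793
fit <- train_model(mod, ds$train, config = train_config(epochs = 5, seed = 7))
fit$history$train_loss
#> [1] 0.7386409 0.5994214 0.5748605 0.4829735 0.4252303

# 3. compare against the untrained twin on held-out phantoms
held <- lapply(1:16, function(i)
  generate_phantom(phantom_config(image_size = 64, seed = 20000 + i)))
evaluate_model(build_model(model_config("fpn_la", seed = 5)), held)$mean$dsc
#> [1] 0.05491343
evaluate_model(fit, held)$mean$dsc
#> [1] 0.2782048
```

The lung mask recovered by the preprocessing chain overlaps the phantom's
true lung fields with IoU ≈ 0.96, and five epochs of BCE-Dice training
already lift the mean held-out Dice coefficient from ≈ 0.05 (random
initialization) to ≈ 0.28. Longer schedules continue to improve it; the
configuration mirroring the reference setup (Adam, learning rate 1e-5,
weight decay 1e-4, batch 8, 200 epochs) is the `train_config()` default.

## Command line

A thin launcher over `run_cli()` is installed under `inst/scripts`:

```sh
Rscript inst/scripts/noduleseg generate --n 8 --seed 1 --out phantoms/
Rscript inst/scripts/noduleseg preprocess --image phantoms/image_0001.png --out pre/
Rscript inst/scripts/noduleseg train --arch fpn_la --n 64 --size 64 --epochs 5 --seed 1 --out run/
Rscript inst/scripts/noduleseg evaluate --model run/checkpoint.rds --n 64 --size 64 --seed 1 --out eval/
Rscript inst/scripts/noduleseg predict --model run/checkpoint.rds --image phantoms/image_0001.png --out mask.png
```

All subcommands accept `--seed` and are reproducible under it; `train` and
`evaluate` also take a YAML configuration (`--config`, schema in
`default_run_config()`).

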