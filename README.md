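# rgbdweight

Non-contact estimation of animal body weight from paired top-view RGB and
depth images, for precision-livestock researchers and engineers who want a
fully inspectable, CPU-trainable reference implementation of a two-stream
cross-modality fusion network — plus a synthetic RGB-D scene generator so
the entire train/evaluate/ablate pipeline runs end to end with no external
data.

## The model

A color branch and a depth branch share a six-stage convolutional encoder
topology. In stages 1–4 a **cross-modality feature supplementation** (CFS)
block exchanges information bidirectionally. Its core is a feature-fusion
(FF) step on the per-stage features *f*<sub>R</sub>, *f*<sub>D</sub>:

> f̄<sub>M</sub> = Conv<sub>1×1</sub>(f<sub>M</sub>),  f̄<sub>F</sub> = f̄<sub>R</sub> ⊗ f̄<sub>D</sub>,
> f<sub>F</sub> = DSConv<sub>3×3</sub>([ f̄<sub>F</sub> + f̄<sub>R</sub>, f̄<sub>F</sub> + f̄<sub>D</sub> ])

(⊗ element-wise product, [·,·] channel concatenation, DSConv a
depthwise-separable convolution), followed by attention-gated
supplementation of each branch:

> bf<sub>R</sub> = f<sub>R</sub> + σ(BAM(f<sub>R</sub>)) ⊗ f<sub>F</sub>,  bf<sub>D</sub> = f<sub>D</sub> + σ(BAM(f<sub>D</sub>)) ⊗ f<sub>F</sub>

where BAM is a bottleneck attention module (parallel channel and spatial
paths, pre-sigmoid logits). Stages 5–6 are weight-shared between the
branches. A decoder aggregates the two feature pyramids coarse-to-fine
through three cross-modality feature-fusion (CFF) levels — within-branch FF
of adjacent scales, across-branch FF, concatenation of the coarser level's
output, receptive-field-block refinement — and a GAP + MLP head regresses
the weight in kg. Evaluation uses MAE, RMSE and R².

Everything below the API — convolution kernels (C++/Armadillo im2col),
reverse-mode autodiff, AdamW — is implemented in the package itself; no
deep-learning framework is required. See
`vignettes/weight-estimation.Rmd` for the full account of the model,
the synthetic data design, and every numerical choice.

## Worked example

Generate a small synthetic dataset, train a width-reduced model on CPU,
and evaluate:

```r
library(rgbdweight)

man <- generate_dataset(512, seed = 11, out_dir = "ds", resolution = 64)
man <- split_manifest(man, 416, 96, seed = 12)
attr(man, "dir") <- "ds"

mcfg <- model_config(input_size = 32, widths = c(8, 12, 16, 16, 24, 32),
                     bam_reduction = 4, bam_dilation = 2, decoder_width = 16,
                     head_hidden = 32, target_norm = TRUE)
tcfg <- train_config(epochs = 10, batch_size = 32, lr = 1e-3,
                     weight_decay = 0.01, seed = 5, augment = FALSE)

fit <- train(man, mcfg, tcfg, out_dir = "run")
evaluate(fit$checkpoint, man, "test")$report
```

```
n    : 96
MAE  : 0.3046 kg
RMSE : 0.3791 kg
R2   : 0.9298
```

The model explains ~93 % of the held-out weight variance over the
0.50–5.50 kg range after ~70 s of CPU training: each scene's weight is the
product of a volume readable only from depth and a density readable only
from the color hue, so a single-modality model cannot reach this accuracy
(compare `run_ablation("modality", c("rgbd", "rgb", "depth"), ...)`).
`gradcam(fit$checkpoint, pair, "decoder.low")` returns a normalized
attention heatmap for one sample.

A thin CLI over the same functions lives at `inst/cli/rgbdweight.R`
(subcommands `generate`, `split`, `train`, `eval`, `gradcam`).

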