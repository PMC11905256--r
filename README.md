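# sadglf

Semi-supervised domain adaptation (SSDA) for 3D abdominal multi-organ
segmentation in R. The package is for method developers and students who
want a complete, CPU-runnable reference implementation of an SSDA
segmentation pipeline: a 3D UNet whose encoder uses **scale-aware blocks
with domain-specific batch normalization** (SAD), whose bottleneck fuses a
local convolutional path with a **patch-transformer global path** (GLF),
trained with a **self-ensembling mean teacher** (SE-MT) on three data
pools — labeled source volumes (SL), a small labeled target subset (TL)
and unlabeled target volumes (TU).

## The model in brief

- **DSBN**: each normalization layer keeps per-domain statistics and
  affines, `y_d = kappa_d * (x_d - mu_d)/sqrt(sigma_d + delta) + theta_d`;
  all convolution/attention weights are shared across domains.
- **SAD block**: Conv-D → [3×3×3 branches with dilation 1 and 3, each with
  squeeze-and-excitation] → concat → channel shuffle → Conv-D
  (Conv-D = conv + DSBN + ReLU).
- **GLF bottleneck**: local path (3×3×3 → 1×1×1 conv, width d = C/2) ∥
  global path (project to d → unfold into 2×2×2 patches → 4 pre-norm
  transformer layers over the N patch positions, d_head = 8, no positional
  embeddings → fold) → concat → 3×3×3 + 1×1×1 fusion convs.
- **SE-MT**: teacher = EMA of the student (decay 0.99); loss
  `L = L_sup + lambda_eff(k) * L_un` with
  `L_sup = 0.7*(1 - soft Dice) + 0.3*CE` on SL ∪ TL,
  `L_un` = student/teacher MSE on TU under independent input noise, and
  `lambda_eff(k) = 2.0 * exp(-5 (1 - k/k_max)^2)` (Gaussian warm-up).
- **Training recipe**: AdamW, lr 0.0009, weight decay 5e-5, lr × 0.95
  every 250 iterations, batches of 4 SL + 2 TL + 2 TU.

Every forward *and backward* pass is implemented in the package (compiled
im2col/GEMM convolution kernels plus vectorized R), so the whole pipeline
— data synthesis, preprocessing, training, evaluation — runs on one CPU at
phantom scale. Evaluation reports per-organ Dice (DSC) and average
symmetric surface distance (ASD, mm), with paired t-tests for method
comparisons. A two-domain phantom generator emulates the study conditions
(intensity-distribution mismatch between modalities, per-patient organ
scale variation) so everything is testable without the CHAOS/BTCV
datasets.

## Worked example

```r
library(sadglf)

spec <- phantom_spec(seed = 1)                 # 16 x 32 x 32 two-domain phantoms
data <- generate_dataset(spec, n_source = 8, n_target = 10,
                         labeled_ratio = 0.2, seed = 11, n_test = 4)
lengths(data[c("SL", "TL", "TU", "test")])
#>   SL   TL   TU test
#>    8    2    8    4

fit <- train_preset(data, preset = "full", steps = 100, seed = 11,
                    opt_args = list(lr = 0.006))
tail(fit$history[, c("step", "loss_total", "loss_sup", "loss_cons",
                     "lambda_eff")], 1)
#>     step loss_total loss_sup  loss_cons lambda_eff
#> 100  100   1.457732 1.422025 0.01785363          2

df <- evaluate_cases(fit$model, data$test, domain = "target")
round(mean(case_average_dsc(df)), 3)
#> [1] 0.229
```

The history shows the loss decomposition per step (`loss_total =
loss_sup + lambda_eff * loss_cons`; `lambda_eff` has ramped to its final
value 2 at the last step). The evaluation table has one row per test case
per organ; `case_average_dsc()` gives the case-level four-organ average.
At this desk scale (100 steps, ~25k-parameter preset network) the mean
test Dice of 0.229 simply shows training under way; the matched
supervised-only baseline on the two TL cases reaches 0.197 on the same
split, the directional gap the mean-teacher setup is designed to produce. The same
pipeline runs from the shell:

```sh
Rscript inst/cli/sadglf synth --seed 7 --n-target 10 --labeled-ratio 0.2 --out data/
Rscript inst/cli/sadglf train --manifest data/manifest.csv --preset full --out run/
Rscript inst/cli/sadglf evaluate --manifest data/manifest.csv \
    --checkpoint run/checkpoint.rds --out run/eval/
```

## Package layout

- `R/synthetic.R` — two-domain phantom generator and SL/TL/TU/test splits
- `R/io_preprocess.R` — NIfTI I/O, clip/crop/resample/normalize, online
  augmentation (±30° rotations, ±0.1 rad shear, gamma 1.5–2)
- `R/dsbn.R`, `R/sad.R`, `R/glf.R`, `R/segnet.R` — the network, with
  hand-derived backward passes
- `R/losses.R`, `R/optim.R`, `R/mean_teacher.R` — losses, AdamW, the
  mean-teacher training engine
- `R/metrics.R` — DSC, ASD, aggregation, paired t-tests
- `R/cli.R`, `inst/cli/sadglf` — command-line entry points and the
  component-ablation presets (baseline, comb1–comb4, full)
- `vignettes/methods.Rmd` — the model, its assumptions, and every design
  decision the architecture description left open
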