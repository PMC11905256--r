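---
title: "Semi-supervised domain adaptation for 3D multi-organ segmentation: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised domain adaptation for 3D multi-organ segmentation: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Abdominal multi-organ segmentation models trained on one imaging modality
(say, CT) degrade badly on another (say, T2-SPIR MRI): the two modalities
map the same anatomy to very different intensity distributions, and organ
scale varies across patients. Annotating target-modality volumes is
expensive, so the practical setting is *semi-supervised domain adaptation*
(SSDA): a well-annotated source-domain set `SL`, a small annotated
target-domain set `TL`, and a larger unannotated target-domain set `TU`.
This package implements an SSDA segmentation framework for that setting,
with four foreground classes (liver, right kidney, left kidney, spleen)
plus background.

## The model

The backbone is a 3D UNet. Three components address the three obstacles:

**Domain-specific batch normalization (DSBN).** Every normalization layer
in the encoder keeps one set of batch statistics and affine parameters per
domain; a batch is normalized by its own domain's statistics,

\[ \tilde y_d = \frac{x_d - \mu_d}{\sqrt{\sigma_d + \delta}}, \qquad
   y_d = \kappa_d \tilde y_d + \vartheta_d , \]

while all convolution and attention weights are shared across domains. The
intensity shift between modalities is absorbed by the normalization, and
the shared weights learn modality-invariant structure. We read the
denominator as the square root of the variance plus \(\delta = 10^{-5}\)
(the standard reading of the normalization formula) and use running-stat
momentum 0.1; affine parameters are per-domain, following their subscripts.

**Scale-aware blocks (SAD).** Each encoder stage is a block
Conv-D → [two dilated 3×3×3 branches, dilation 1 and 3, each with an SE
channel-recalibration] → concatenation → channel shuffle → Conv-D, where
Conv-D is convolution + DSBN + ReLU. The two dilation rates give matched
feature depth at two receptive-field sizes, so small kidneys and a large
liver are both represented; the SE blocks re-weight channels per sample and
the shuffle mixes the two scales. Each branch outputs half the block width
so the concatenation restores it (branch widths are not dictated by the
architecture description; halving is the symmetric choice). SE blocks use
independent weights per branch, reduction 4; shuffle groups = 2, one per
branch.

**Global–local fusion bottleneck (GLF).** At the bottleneck a local path
(3×3×3 conv → ReLU → 1×1×1 conv, width \(d = C_{in}/2\)) runs in parallel
with a global path: 1×1×1 projection to width \(d\), unfolding into
non-overlapping 2×2×2 patches giving a token tensor of shape
\((P, N, d)\) with \(P = 8\) and \(N = DHW/P\), then \(L = 4\) pre-norm
transformer layers

\[ z' = \mathrm{MHA}(\mathrm{LN}(z)) + z, \qquad
   z = \mathrm{MLP}(\mathrm{LN}(z')) + z' \]

with attention over the \(N\) patch positions (softmax over keys, scaled by
\(1/\sqrt{d_{head}}\), \(d_{head} = 8\)) and no positional embeddings, and
finally folding back. The two paths are concatenated (2\(d\) channels) and
fused by a 3×3×3 then a 1×1×1 convolution. Two points were genuinely open
and are fixed here as design choices: (i) the fusion order — we concatenate
the local tensor with the folded global tensor and apply the shared
convolutions afterwards, the only composition consistent with the declared
tensor shapes; (ii) the head count, never stated, is derived as
\(n_{head} = d / d_{head}\). The within-patch index is treated batch-like,
matching the printed token shape \((B, P, N, d)\); GLF's convolutions carry
no normalization, and the MLP uses GELU with expansion factor 2.

**Mean-teacher training (SE-MT).** A student is trained by AdamW; a
teacher of identical topology is the exponential moving average of the
student, \(\Theta'_k = \eta\,\Theta'_{k-1} + (1-\eta)\,\Theta_k\) with
\(\eta = 0.99\), never updated by gradients. Each step draws 4 `SL`, 2
`TL` and 2 `TU` samples; the supervised loss on `SL` and `TL` is
\(\lambda_{dice}(1-\text{soft Dice}) + \lambda_{ce}\,\text{CE}\) with
\(\lambda_{dice} = 0.7\), \(\lambda_{ce} = 0.3\); the consistency loss is
the MSE between student and teacher probability maps on the same `TU`
inputs under different noise. The total loss is
\(L_{sup} + \lambda_{\mathrm{eff}}(k)\, L_{un}\).

### The consistency-weight ramp

The training recipe specifies a time-dependent Gaussian warm-up
\(0.1\,e^{-5(1-k/k_{max})^2}\) and, separately, a tuned trade-off
\(\lambda = 2.0\). We reconcile the two the way mean-teacher
implementations conventionally do: the warm-up is the *shape* of the
time-dependent consistency weight, normalized so that its final value is
the tuned \(\lambda\):
\(\lambda_{\mathrm{eff}}(k) = \lambda\, e^{-5 (1-k/k_{max})^2}\).
Both the amplitude (0.1) and \(\lambda\) remain available in
`loss_weights()`; `consistency_weight()` is the raw ramp, which equals
exactly 0.1 at \(k = k_{max}\) and \(0.1e^{-5}\) at \(k = 0\).

### Noise for the consistency term

The consistency loss compares voxel-wise predictions, so the student and
teacher must see *geometrically identical* inputs: independently drawn
rotations would misalign the two probability maps and the MSE would
compare different anatomy. We therefore draw one augmentation per `TU`
sample per step (shared geometry) and realize the two noise draws
\(\Delta, \Delta'\) as independent additive Gaussian input noise with sd
0.05.

## Optimization

AdamW with initial learning rate 0.0009 and weight decay 0.00005; the
learning rate decays by 0.95 every 250 iterations (stepwise exponential).
Gradients are clipped at global norm 5, and a non-finite loss aborts with a
diagnostic rather than continuing. The teacher is initialized as a copy of
the student; the deliverable of training is the student. When `TU` is
empty, or \(\lambda = 0\), or the mean-teacher flag is off, the consistency
branch is disabled *structurally* — no teacher forwards, no extra RNG
draws — so such a run is bit-identical to a plain supervised run with the
same seed.

All forward and backward passes are implemented in this package: compiled
im2col/GEMM convolution kernels (single-precision GEMM internally,
double-precision tensors at the R surface) with hand-derived gradients for
every layer, verified in the test suite against brute-force convolution
oracles and exact adjoint identities.

## The synthetic phantom generator

Real CHAOS/BTCV volumes cannot ship with a package, so the generator
produces the *statistical situation* the method assumes, not anatomy: four
axis-aligned ellipsoidal organs at anatomically inspired anchor positions
on a `(D, H, W) = (16, 32, 32)` grid with anisotropic spacing (7, 1.5,
1.5) mm (thick slices, as in abdominal T2-SPIR). Per case, each organ's
fractional radius is drawn from its range (liver 0.16–0.22, kidneys
0.07–0.10, spleen 0.10–0.14) and its center jittered by ±0.03 —
the across-patient scale variation the scale-aware blocks target. The two
domains share the geometry model but map classes to different intensities
(source: CT-like, kidneys brightest, tissue sd 0.02; target: T2-like,
liver brightest, kidneys dark, sd 0.05), plus additive scanner noise
(sd 0.02) and per-volume min-max normalization. The defaults are chosen so
that every class's mean normalized intensity differs between domains by
far more than its standard error — the domain shift is real by
construction, and asserted in the tests. What the phantoms deliberately
lack: realistic organ shape and texture, partial-volume effects, imaging
physics, inter-organ contact surfaces. Passing the phantom-scale tests
therefore demonstrates that the machinery (architecture, losses, training
dynamics, metrics) is correct, not that the method reaches any particular
accuracy on real data.

Per-case seeds are derived from the dataset seed and case index by a
multiplicative mixing (`mix_seed()`), so datasets are reproducible
element-wise and all streams stay below \(2^{31}\).

## Preprocessing and augmentation

The ingestion chain is clip → crop → resample → normalize: CT intensities
are clipped to [−350, 350] (no clipping for MRI; percentile clipping would
be a plausible alternative), the volume is cropped to the union bounding
box of the foreground labels plus a margin (for unlabeled volumes, an
intensity-threshold body-mask box — the cropping rule is not prescribed
beyond "crop to the targeted organs"), resampled trilinearly (labels:
nearest neighbour, so no interpolation classes appear), and min-max
normalized to [0, 1]. Clipping before cropping is intensity-order-invariant
with these bounds; the order is fixed here for reproducibility. Online
augmentation draws a rotation in ±30°, a shear in ±0.1 rad and a gamma in
[1.5, 2] (applied as \(v^\gamma\) on [0, 1], image only). Rotations and
shears are in-plane (H, W): with 7 mm slices against 1.5 mm in-plane
resolution, through-plane rotation of a 16-slice stack is not meaningful.

## Problem sizes used by the tests

The default network configuration is 4 encoder stages with base width 16.
The tests and the end-to-end checks use the phantom-scale preset
(`phantom_net_config()`: 2 stages, widths 8/16, bottleneck 32, ~25k
parameters) on the 16×32×32 grid — the same topology family, sized so a
complete training run takes minutes on one CPU. The desk-scale training
checks use a learning rate of 0.006 rather than the full-scale recipe's
0.0009: the recipe value belongs to a 200-epoch schedule on 256×256×32
volumes, while the smoke checks must converge within a few hundred steps
on a 25k-parameter network; the schedule's *shape* (0.95 decay every 250
iterations) is kept and asserted separately. The end-to-end checks are:
single-case overfitting (200 steps, foreground Dice > 0.8) and a
directional comparison — on 3 seeded datasets (8 source cases, 10 target
training cases at 20% labeled ratio, 4 test cases), the full method's mean
test Dice must be at least that of supervised training on the two `TL`
cases alone at a matched 100-step budget. The comparison is directional
only; phantom-scale Dice values say nothing quantitative about CHAOS/BTCV
performance.

## Evaluation

Per-organ Dice similarity coefficient and average symmetric surface
distance. Surfaces are 6-connectivity boundary voxels (array border counts
as boundary); distances are exact nearest-neighbour distances in physical
millimetres at the preprocessed grid's spacing. Conventions the metric
definitions leave open: Dice is 1 when both masks are empty and 0 when
exactly one is; ASD with an empty surface is *flagged undefined* (`NA`
with attribute), never silently zero. Method comparisons use two-sided
paired t-tests on case-level organ-averaged scores; zero-variance
differences are flagged rather than tested.

## Known limitations

- Phantom geometry is ellipsoidal; no contact between organs, so boundary
  localization is easier than in real anatomy.
- The within-patch attention axis is vectorized batch-like; a variant that
  attends within patches is not implemented.
- Decoder normalization is shared across domains by default (the
  domain-specific scheme is specified for the encoder path);
  `dsbn_decoder = TRUE` enables it everywhere.
- Two domains only; more would require generalizing the DSBN state.
- The compiled kernels are single-threaded; training wall-time scales
  linearly with batch and voxel count.
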