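---
title: "Methods: volumetric SAT/VAT segmentation on synthetic Dixon MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: volumetric SAT/VAT segmentation on synthetic Dixon MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the synthetic data, and the numerical
and design choices behind `adiposeg`. Nothing here states an empirical
result beyond what the test suite and `scripts/acceptance.R` compute.

## The segmentation problem

Abdominal adipose tissue splits into a subcutaneous ring (SAT) and
scattered visceral components between the organs (VAT). On two-point
Dixon MRI the fat image F is bright in both compartments, and so are
non-adipose confounders such as vertebral bone marrow — which reference
annotation protocols remove by hand. Intensity alone therefore cannot
produce a correct VAT mask; the segmenter needs spatial context, which is
why the package implements full field-of-view volumetric networks: the
entire multi-contrast stack (opposed-phase, water, fat) is processed in a
single forward pass, with no slice-wise or patch-wise decomposition that
would truncate in-plane or through-plane context.

## Network families

All three families share the encoder/decoder U-Net topology with skip
concatenations, two 3×3×3 convolutions per resolution level, and a 1×1×1
convolution + softmax head over three classes (background, SAT, VAT).

* `unet3d`: widths 64/128/256/512, batch normalization + ReLU, 2×2×2
  max-pooling, 2×2×2 transposed-convolution upsampling. This fixes
  22,403,011 trainable parameters (verified against a closed-form
  layer-by-layer sum in the tests), the scale at which the two-convs-per-
  level choice is locked.
* `acd_unet3d`: the same skeleton with *competitive dense* blocks — the
  two feature stacks a block produces compete through an element-wise
  maximum (maxout), holding the channel width constant instead of growing
  it by concatenation — plus a channel-then-spatial attention gate at the
  bottleneck only. The channel gate is a squeeze-excitation MLP (reduction
  ratio 8, shared over average- and max-pooled channel descriptors); the
  spatial gate is a 3×3×3 convolution over the channel-mean and
  channel-max maps; both gates are sigmoids applied multiplicatively. The
  published block internals are not fully specified, so the block sits
  behind a single interface (`net_block`) and can be swapped; with this
  parameterization the ACD variant counts 22.47 M parameters, which is a
  reported diagnostic of this reconstruction, not a target.
* `nnunet_like`: the resolved self-configured profile — instance
  normalization, leaky ReLU (negative slope 0.01), strided-convolution
  downsampling, transposed-convolution upsampling, widths starting at 32,
  doubling per stage, capped at 320. The default stage count is 6 (five
  pooling transitions), which takes a 192×192 in-plane matrix down to 6×6
  and yields 31.2 M parameters; the slice axis is only pooled while it
  still has at least 8 slices, reflecting the strong anisotropy of
  abdominal stacks (5 mm slices vs 2.08 mm in-plane).

Inputs whose extents are not divisible by the cumulative pooling factors
are zero-padded symmetrically and cropped back after the head; the
bottleneck must retain at least 2 voxels per axis or construction errors
out. Weights are He-initialized from the config seed; biases start at 0,
normalization scale/shift at 1/0.

### The engine

No deep-learning framework is involved: convolutions are im2col
transforms (C++ kernels with persistent scratch buffers) feeding BLAS
`dgemm`, and gradients are computed by a small reverse-mode tape whose
every operator carries a hand-written adjoint. The full network gradient
is verified against central finite differences for all three families in
the development process, and the test suite checks the training loop
end-to-end (loss decrease, overfitting capacity, determinism). With
batch-size-n training the gradients of n consecutive volumes are
averaged before the optimizer step; normalization statistics are computed
per volume (with batch normalization keeping running moments for
inference). Element-wise maxima (maxout, max-pooling, attention max
descriptors) break ties toward the first operand / lowest index, so runs
are bit-reproducible on one device.

## Losses

Both losses act on the softmax probabilities; no hard argmax appears
inside, so they are differentiable everywhere. Per class $l$ with voxel
weights $m_n$,

$$D_l = \frac{2\sum_n m_n p_{ln} r_{ln} + \varepsilon}
             {\sum_n m_n p_{ln} + \sum_n m_n r_{ln} + \varepsilon},
\qquad \mathrm{loss} = 1 - \sum_l w_l D_l, \quad \sum_l w_l = 1 .$$

* **WDL** — uniform $w_l$ over the included classes, $m \equiv 1$.
  Whether the original weighted Dice loss used uniform or frequency
  weights is not documented; uniform is the default and the weights are
  configurable.
* **FBDL** — $w_l \propto 1/\mathrm{freq}_l$ with the frequency taken
  either over the whole training set (default; stable) or per batch, and
  $m_n = 1 + (\beta-1)$ on voxels within $d$ voxels of a reference label
  boundary (6-connected morphological gradient of the one-hot reference,
  dilated to band width $d$; defaults $\beta = 2$, $d = 1$). The exact
  published functional form of FBDL is not reprinted anywhere accessible,
  so this is a reconstruction from the loss's name and stated purpose;
  the frequency and boundary components are isolated behind the config so
  alternative published forms can be substituted. With $\beta = 1$ and
  equal class frequencies FBDL reduces exactly to uniform WDL (tested).

Numerical choices: smoothing $\varepsilon = 10^{-5}$ in numerator and
denominator (so a perfect prediction scores a loss of order
$\varepsilon$, and an absent class contributes $D_l = 1$ rather than
0/0); absent-class frequencies are floored at one voxel equivalent so
inverse-frequency weights stay finite; background is included in the Dice
sum by default so background false positives remain penalized.

## Synthetic Dixon phantom

The generator emulates the acquisition the method targets: axial
T1-weighted dual-echo Dixon stacks, 192×192 over a 400 mm field of view
(2.08 mm in-plane), 5 mm slices, 51 analyzed slices selected as a
landmark slice plus 50 superior slices (255 mm span). Per slice the torso
is an ellipse (default semi-axes 170×125 mm, mild quadratic taper along
z); SAT is an annulus whose thickness (default 20 mm) is modulated over
angle and slice; the cavity interior is water-dominant lean tissue; VAT
is the superposition of Gaussian components thresholded at the quantile
that meets the target fill fraction (default 0.30 of eligible cavity
voxels) exactly up to one voxel — giving tunable spatial complexity with
exact ground truth. A vertebral-marrow cylinder and optional bowel-fat
specks carry exactly the SAT fat signal but are labeled background, so no
intensity threshold can reproduce the reference; this is what makes the
phantom task informative about spatial learning.

The signal model is the magnitude two-point Dixon forward model:
$F = f + n$, $W = w + n$, $TE_{IP} = w + f + n$, $TE_{OP} = |w - f| + n$,
with independent additive Gaussian noise per channel clipped at zero (a
Rician approximation that keeps the closed-form volume oracles exact at
zero noise). Default intensities are 200 (fat), 100 (water), noise sigma
8 — arbitrary units; real intensity distributions are scanner-dependent
and are deliberately not claimed.

Covariates: an adiposity score (BMI surrogate, sampled N(1, 0.15) in
cohorts and clamped to [0.6, 1.6]) scales the SAT thickness and VAT fill
fraction linearly with coefficient 1; an age-like covariate N(50, 14) has
no geometric effect and exists for split stratification. Longitudinal
pairs re-render the same anatomy (identical torso, component and
confounder placement) with SAT thickness and VAT fill scaled by
$1+\delta$ and fresh noise; the true ΔVolume is recorded. Cohort deltas
default to U(−0.15, 0.15) per tissue, a plausible 6-month change range
under dietary intervention.

What the phantom does **not** emulate: organ anatomy, partial-volume
fat/water mixing, bias fields, respiratory motion, fat–water swaps,
k-space artifacts, scanner-to-scanner intensity variation. Passing the
phantom experiment therefore demonstrates that the pipeline learns
spatial context and quantifies volumes consistently — not that the
networks reach clinical-grade accuracy on patient data.

## Trainer

Splits are stratified by joint covariate quantile bins (tertiles),
with split labels laid out at evenly spread fractional positions and
walked over the bin-ordered subjects, so every bin receives
near-proportional shares; subject counts follow largest-remainder
rounding of the 0.70/0.10/0.20 fractions; both time points inherit the
subject's split. The balance report carries per-split covariate means and
Kruskal–Wallis p-values; an assignment with any p ≤ 0.05 is regenerated
with a new sub-seed (at most 20 retries). Normalization is per-channel
0–255 rescaling for the U-Net arms (each contrast occupies the full
dynamic range independently) and per-channel z-scoring for the
nnU-Net-like arm; constant channels map to zeros rather than erroring.
Optimizers: Adam (default learning rate 1e-4, with 2e-3 used in the
compact experiment after validation-loss comparison at this problem
scale) and Nesterov momentum 0.99 with learning rate 0.01 for the
nnU-Net-like arm. No data augmentation is applied anywhere. Training
tracks validation loss each epoch and returns the parameters (and
normalization state) of the best validation epoch. Evaluation refuses
subject overlap with the training set and performs no weight update, so
time point 2 is scored by the time point 1 model unchanged.

## Statistics layer

Kruskal–Wallis and Wilcoxon signed-rank wrap the tie-corrected standard
implementations; zero paired differences are discarded (classic rule),
an all-zero difference vector reports p = 1, the exact null distribution
is used up to 25 nonzero untied pairs and the continuity-corrected
normal approximation beyond. Benjamini–Hochberg rejects every hypothesis
up to the largest $i$ with $p_{(i)} \le i q / m$ (step-up), with
adjusted p-values reported alongside. ICC uses the two-way,
absolute-agreement, single-measurement form ICC(A,1), computed from the
ANOVA mean squares; absolute agreement was chosen because volume bias
matters for quantification, and the variant is recorded in every result
object (consistency ICC(C,1) is available). Cutpoints for the
qualitative category are 0.5 / 0.75 / 0.9. Medians with IQR use
linear-interpolation quantiles (type 7). Both-empty Dice is defined as 1
(perfect agreement on absence) with a logged message; a degenerate
pooled FP/FN denominator returns 0% with a warning.

## Problem sizes

The shipped experiment (`run_phantom_experiment()`) uses 30 training
(3 of them held out as validation for checkpoint selection) and 10 test
subjects at 64×64×24 voxels (the 400 mm field of view retained, so
6.25 mm in-plane), a base-8 `acd_unet3d` (filters 8/16/32/64), FBDL,
Adam at 2e-3 for 8 epochs — sizes chosen so the whole study runs in
minutes on a single CPU while keeping every structural element of the
full-scale problem: multi-contrast inputs, confounders, class imbalance,
longitudinal pairing. Unit tests use 8³–48³ fixtures; the closed-form
annulus checks run at the native 192×192 in-plane resolution where
voxelization error is a fraction of a percent.

## Known limitations

* The FBDL reconstruction is not claimed to be numerically identical to
  the original formulation.
* The competitive-dense block keeps the plain block's parameter shape;
  published ACD parameter counts differ.
* Batch normalization statistics are per-volume during training
  (gradient accumulation), not cross-volume.
* The phantom's organ interior is homogeneous lean tissue; none of the
  intensity pathologies of real Dixon reconstructions are modeled.
* Single-device reproducibility only; bitwise equality across BLAS
  builds is not promised.
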