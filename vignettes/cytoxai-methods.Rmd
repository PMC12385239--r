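---
title: "Methods: hybrid blood-smear classification with adaptive attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid blood-smear classification with adaptive attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoxai)
```

## The problem

Classifying leukemic white blood cells on stained peripheral blood smears
is a morphology problem: maturation stage shows up as nucleus size,
nucleus-to-cytoplasm (N:C) ratio, and chromatin texture. A clinically
usable classifier must not only label a cell but also justify the label in
terms a hematologist can audit. `cytoxai` implements a hybrid
architecture for this task — a convolutional encoder for local morphology,
a vision transformer for global context, a bounded fusion layer, and a
controller head that chooses, per image, which of four attribution methods
best explains the prediction — together with the full experimental harness
(class balancing, fixed and cross-validated evaluation, ablations) and a
synthetic smear generator so that every stage runs and is testable on one
CPU with no external data.

## Model

Input images are `side x side x 3` arrays in `[0, 1]`.

**Convolutional encoder with morphological attention.** A stack of
stride-2 convolution / batch-norm / ReLU stages produces a feature map
`F` of shape `H' x W' x C`. A channel gate then pools `F` spatially
(`z_c = mean(F[, , c])`), computes `w = sigmoid(W2 relu(W1 z))`, and
rescales each channel: `F_att[, , c] = F[, , c] * w_c`. The gate is
bias-free, so zero weights give `w = 0.5` exactly — a closed form the
tests pin down. Global average pooling of `F_att` yields `f_cnn`.

**Transformer branch with conceptual attention.** The image is cut into
non-overlapping `P x P` patches, flattened, linearly projected to width
`D`, prefixed with a learnable class token and summed with learnable
positional encodings. `L` pre-norm encoder blocks (LayerNorm,
multi-head self-attention, residual; LayerNorm, GELU MLP, residual) and a
final LayerNorm refine the tokens. Pooling is not the class token but a
learned soft attention over all tokens: each token is scored
`v' relu(W t_i)`, the scores are softmax-normalized to weights `alpha`
on the simplex, and `f_vit = sum_i alpha_i t_i`. With `v = 0` the weights
are uniform; the pooled vector always lies in the per-coordinate convex
hull of the tokens.

**Bounded fusion ("logic bridge").** The pooled vectors are concatenated
and passed through the bias-free two-layer map
`f_bridge = tanh(W2 relu(W1 [f_cnn || f_vit]))`, a 256-wide vector with
entries strictly inside `(-1, 1)`. The bounded range is what licenses the
fuzzy-rule reading of the fused features (each coordinate as a graded
truth value); the package renders that reading as explicit IF–THEN text
via `verbalize_rules()`, which is presentation only.

**Heads.** The classifier is `softmax(W2 relu(W1 f_bridge) + b)` (bias on
the output layer only). The controller head maps the same 256-wide vector
through a 64-unit ReLU MLP with biases to a softmax over the four
attribution methods, in the fixed order `grad_cam, shap,
integrated_gradients, lime` (`xai_methods()`); the order is part of the
contract because policy indices are meaningless without it.

**Profiles.** `model_config("tiny")` (3 conv stages, 16/32/32 channels at
stride 8; patch 8, width 64, depth 2, heads 4) is the desk profile every
test and example uses. `model_config("b0")` reproduces the full-scale feature
contracts — a stride-32 encoder ending at C = 1280 and a transformer with
patch 16, width 768, depth 6, heads 8, input 128 px — so pooled widths are
1280 and 768 and the fused width 256. The depth/heads of the full-scale
transformer and the gate and bridge hidden widths are not pinned by the
architecture's published equations; they are configuration with defaults
(gate reduction 16 in the squeeze–excitation convention with a floor of
4 hidden units; bridge hidden 256 tiny / 512 b0; classifier hidden 256),
not constants. The 256-wide tiny heads are deliberately wider than the
minimum the equations allow: at a fixed learning rate, narrow heads
jitter visibly at the class boundaries late in training, and the extra
width damps that without touching the optimizer preset.

## Training

The composite loss is cross-entropy plus an explanation-quality term,
`L = L_CE + lambda_x * (1 - mean_b sum_k p_bk q_bk)`, which rewards
policies that weight methods currently producing good explanations.
`lambda_x` defaults to 0.1. The quality signal `q` is the mask IoU of each
method's attribution against the synthetic nucleus ground truth when masks
exist, else a deletion-fidelity score. Because `q` changes slowly while
computing four attribution methods is orders of magnitude more expensive
than a gradient step, `q` is recomputed once per epoch on a small
subsample (`quality_n = 4` images, with reduced method budgets) and held
fixed within the epoch; the policy head still receives a gradient every
step. Per-batch recomputation would change `q`'s freshness, not its
meaning.

Three optimizer presets are provided: SGD (learning rate 0.01, momentum
0.9), Nadam (1e-3), and rectified Adam at 5e-4 with a power-law
"fractional" decay `lr_t = lr0 * (1 + t)^(-q)`, exponent 0.5 by default;
exponent 0 reduces it to plain rectified Adam, which the test suite uses
as a differential oracle. Training runs a fixed number of epochs
(default 10, batch 32), records train/validation accuracy and loss every
epoch, re-initializes the model from the seed at the start of each call,
and saves the final state when a checkpoint path is given. Updates are
bounded by adaptive gradient clipping (each parameter array's gradient is
capped at 0.5 times the array's own norm, configurable via `agc_lambda`):
with momentum 0.9 an occasional large step can otherwise throw the
small-scale transformer projections far outside their operating range,
from which recovery is slow. The reported model is not the raw final
iterate but a per-epoch Polyak–Ruppert average: within each epoch the
parameter iterates are averaged uniformly, and the fitted model is the
last epoch's average with batch-norm buffers recalibrated over the
training set (`ema_decay = "epoch"`, with a conventional exponential
moving average also available). Averaging removes most of the step-level
oscillation a fixed learning rate with high momentum leaves behind.

Two numerical choices deserve note. First, the conv stages carry batch
normalization: without it the globally pooled features vary by only a few
percent between samples (smear images are mostly background), the fused
vector is nearly constant across a batch, and the heads sit at the
uniform-prediction stationary point — with per-channel batch
standardization the between-sample variation is O(1) and training takes
off. Inference uses running statistics, so fitted models are
deterministic. Second, weights feeding saturating nonlinearities (the
gate's sigmoid, the bridge tanh, the softmax heads) are Xavier-initialized
while ReLU-fed weights are He-initialized; He-scale weights into the tanh
saturate it after the first optimizer steps. The transformer follows the
standard ViT recipe — projections at normal(0, 0.02), residual outputs
scaled by `1/sqrt(2L)` — and uses QK normalization: queries and keys are
L2-normalized per head with a fixed temperature `sqrt(d_h)`, so attention
logits are bounded no matter how large the projections grow. Without
QK normalization the attention landscape sharpens as training
progresses and momentum SGD oscillates violently mid-run; with it the
trajectories are stable (the package's own stability diagnostics, run on
the synthetic study conditions, drove all three choices). One further
initialization choice balances the two branches: the transformer half of
the first fusion weight matrix starts scaled by 0.25, so the initially
uninformative transformer features cannot drown the pooled morphology
features during the first epochs.

The whole network and its backpropagation are implemented in base R
matrix code (im2col convolutions, hand-derived backward passes for every
layer including batch norm, attention and the concept pooler). Every
backward pass is verified against central finite differences in the test
suite; the analytic gradients agree to the order of the finite-difference
truncation error.

## Evaluation harness

`fixed_split()` makes a stratified, seeded 80/20 split; `kfold_split()`
makes stratified 5-fold partitions (stratification is the default — the
experimental summary of the original protocol lists stratified folds, and
it removes a source of variance at desk scale). `evaluate()` computes
accuracy, macro and support-weighted precision/recall/F1, the confusion
matrix (rows = truth) and ROC-AUC — rank-based (Mann–Whitney) for two
classes, unweighted one-vs-rest macro for more; the one-vs-rest scheme is
a package choice since the source protocol plots multi-class ROC curves
without naming one. Undefined precision or recall (a class never
predicted, or with no support) scores 0 with a warning; this convention is
required to reproduce degenerate collapse patterns (a balanced binary set
predicted all-one-class gives accuracy 0.5 and macro F1 1/3).
`cross_validate()` re-initializes model and optimizer per fold and
aggregates by the unweighted fold mean. `ablate()` produces the six
standard configurations (`full`, `no_bridge`, `no_meta_xai`, `no_morph`,
`no_vit`, `cnn_only`); `profile_model()` reports exact parameter counts
and closed-form MAC estimates.

## Attribution methods

All four methods run against a minimal model interface (logits, input
gradients, last-conv activations/gradients), so they work on fitted
networks and on closed-form toy models alike (`manual_model()`), which is
how the oracle tests drive them.

- **Grad-CAM**: channel weights are the spatial means of the
  explained-class logit's gradient at the last conv block; the map is the
  rectified weighted activation sum, bilinearly upsampled for display.
  Upsampling and any `[0,1]` rescaling are presentation-only.
- **Integrated Gradients**: midpoint-Riemann path integral from a
  baseline (black image by default, steps default 64), scaled by
  `(input - baseline)`. The completeness gap is computed and attached to
  every map; on smooth models it falls below 1% of the logit change by
  256 steps.
- **SHAP**: `shap_exact()` enumerates all coalitions with the exact
  combinatorial weights (guarded to 12 features);
  `shap_gradient()` is the expected-gradients sampler over a background
  set, exact for linear models and converging (segment-summed) to the
  exact values on coarse-feature games.
- **LIME**: grid superpixels by default (deterministic and
  test-friendly; the source method names no segmentation algorithm),
  perturbations fill masked segments with the image mean colour, the
  proximity kernel is Gaussian in the masked fraction, and the sparse
  surrogate is solved by coordinate descent on the weighted
  L1-penalized least squares. At zero penalty it matches the
  normal-equations solution to 8 decimals.

One behaviour worth knowing when reading the maps: for classes defined
by a *small* nucleus, a correctly working Grad-CAM highlights the ring
where a larger nucleus would have been — the class evidence is the
absence of nucleus signal, so the map is an annulus around the nucleus
rather than a disc on it, and its mask IoU is legitimately near zero.
On the large-nucleus classes the same model's maps sit squarely on the
nucleus (median IoU ≈ 0.73–0.78 against ≈ 0.11–0.19 for a shuffled-map
control on the synthetic study conditions). Localization claims should
therefore be evaluated across all classes, not on one class's folder.

`explanation_quality()` scores a map either as IoU against a ground-truth
nucleus mask (binarizing the map at the mask's own area quantile) or as
normalized confidence drop after deleting the top 20% attributed pixels.
`select_explanation()` takes the policy argmax with lowest-index
tie-breaking.

## Synthetic smear generator

`render_cell()` draws one cell as layered discs: background at a given
brightness, an elliptical cytoplasm, and a nucleus disc with additive
Gaussian chromatin speckle; the nucleus pixels are returned as a binary
mask. The stain hue interpolates from eosin-pink to basophilic purple.
`smear_spec()` + `generate_dataset()` write per-class folders of PNGs
plus masks and a manifest CSV. Each image derives its own RNG stream from
`(seed, index)`, so regeneration is byte-identical and order-independent.

The default four-class morphology ladder (`all_morphology()`) increases
nucleus radius fraction (0.12 → 0.32), chromatin granularity
(0.02 → 0.12) and N:C ratio (0.30 → 0.80) from the benign profile to the
most immature blast profile. Only these morphological parameters differ
between classes: stain hue and background brightness are drawn from one
shared distribution for all classes, so colour carries no label
information and a classifier must read shape and texture. (A
class-dependent hue would hand the model a colour shortcut, and the
saliency maps of a colour-shortcut model no longer concentrate on the
nucleus.) The real datasets publish no quantitative
per-subtype morphology, so these are the package's own choices — picked
once to be visually plausible and machine-separable, and not tuned
thereafter. What passing tests show is therefore that the pipeline
learns and localizes *this* morphology; they say nothing about staining
variation, multi-cell scenes, acquisition noise or other properties of
real smears, which the generator deliberately does not model.

## Class balancing

`plan_balance()` computes per-class deficits against the majority class;
`apply_balance()` fills them with augmented copies — rotation up to ±30°,
zoom up to ±20%, horizontal flips, multiplicative brightness 0.8–1.2 —
sampling parameters per synthetic image from a seeded stream. Source
images are chosen by seeded shuffle then round-robin, so every original
is used before any repeats (the source selection rule is unspecified
upstream; round-robin minimizes duplicate-heavy synthetic sets).
Geometric fills use reflect padding to avoid black-corner artifacts a
model could shortcut on; brightness is multiplicative with clipping.
Plan-only mode builds the balanced manifest without touching pixels, so
count-level checks run in milliseconds. Balancing the whole set before
splitting mirrors the source protocol; note that this lets augmented
derivatives of one original land on both sides of a later split, so for
leakage-sensitive work balance only the training side after splitting
(`fixed_split()` first, then `apply_balance()` on the training
manifest) — both orders are supported and neither is asserted as the
original protocol's.

## Problem sizes

The test suite and the acceptance script run everything at desk scale:
synthetic datasets of 3–200 images per class at 32–64 px, the `tiny`
profile (about 276k parameters), 1–10 epochs. These sizes were chosen as
the smallest at which each claim is still meaningfully exercised — e.g.
four classes × 200 images at 64 px trains the tiny profile to roughly
92–96% held-out accuracy (seed-dependent) with the SGD preset from
random initialization, and 50 held-out smears score the
Grad-CAM nucleus localization against a shuffled-map control. Published
headline accuracies on the real public datasets are out of scope: they
require the external downloads and full-scale training, and no number in
this package is asserted against them.

## Known limitations

- The `b0` profile honours the published feature-map contracts (widths,
  strides, 1280/768/256 pooled widths) but is a plain conv stack, not a
  re-implementation of the named backbone, and ships no pretrained
  weights.
- The transformer's full-scale depth/heads are unstated upstream; the
  profile's choices land the parameter count in the published order of
  magnitude but cannot be decomposed against it exactly, so
  `profile_model()` reports counts without asserting that figure.
- Pure-R training is CPU-bound; the desk profile trains in minutes, the
  `b0` profile is provided for architecture fidelity, not routine
  training.
- From random initialization, ten epochs of the constant-rate SGD preset
  end in a limit cycle whose averaged accuracy plateaus around 0.92–0.96
  on the study conditions; the original protocol starts from a
  pretrained, transfer-learned encoder, which this package cannot ship.
  Iterate averaging, adaptive clipping and the initialization choices
  above recover most, but not all, of that gap.
- `shap_gradient()` shares the expected-gradients estimator family with
  gradient explainers, not the kernel/perturbation family; deletion
  fidelity and IoU are the only built-in quality scores.
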