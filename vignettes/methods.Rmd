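---
title: "Group-equivariant onset-time classification: models, phantoms and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-equivariant onset-time classification: models, phantoms and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mismatchnet)
```

## The problem

Intravenous thrombolysis for acute ischemic stroke is licensed only within
4.5 hours of symptom onset, but roughly one in five patients wakes up with
their symptoms and cannot state an onset time. The DWI-FLAIR mismatch sign
is the imaging surrogate used to triage these patients: an acute lesion is
hyperintense on diffusion-weighted MRI (DWI) within minutes, while the
corresponding parenchymal hyperintensity on FLAIR develops only over hours.
A lesion visible on DWI but not on FLAIR therefore suggests onset within
4.5 hours. Human mismatch rating is limited by experience, interrater
agreement, and confounders such as leukoaraiosis and old infarcts.

`mismatchnet` implements an end-to-end deep-learning pipeline for this
classification task: paired DWI/FLAIR volumes in, a probability that onset
was at most 4.5 hours ago out, together with the full clinical evaluation
machinery (calibrated operating points, augmentation of human ratings,
agreement statistics, significance testing) and gradient-based
explanations. Because clinical stroke MRI cannot be redistributed, the
package ships a synthetic phantom generator so that every stage is
exercisable and testable at desk scale.

## The D4h group and equivariant convolutions

Stroke MRI volumes are strongly anisotropic: many thin axial slices with
square in-plane geometry. The exact symmetries of such a grid form the
point group D4h of order 16, generated by

* an in-plane quarter-turn rotation `r` (4 values),
* an in-plane mirror `m` (2 values),
* a through-plane flip `z` (2 values),

with canonical element index `idx = r + 4m + 8z`. `d4h_cayley()` builds the
full composition table by realizing every element as a voxel permutation
and composing the permutations, so the table and the action
(`act_on_volume()`) cannot disagree by construction. The table satisfies
the group axioms exhaustively (16^3 associativity triples are checked in
the test suite) and serializes to JSON for checkpoint integrity checks.

A *lifting convolution* correlates a scalar-channel volume with the kernel
transformed by each of the 16 elements, producing feature maps indexed by
group elements. A *group convolution* maps oriented features to oriented
features using kernels that are both spatially transformed and permuted
along the orientation axis by the group multiplication
(`psi_g(h, u) = psi(g^-1 h, g^-1 u)`). Both satisfy the layer equivariance
contract

```
layer(act(g, input)) == act_on_oriented(g, layer(input))
```

exactly (double precision; the tests use 1e-5 as the tolerance and observe
~1e-14). Orientation pooling (max by default) then yields features that
are invariant up to the spatial transform, and after global average
pooling the classifier score is invariant under all 16 input symmetries.
Kernel transformation is implemented by applying the voxel-permutation
action to the kernel tensor itself (an index-map gather), which guarantees
bit-consistent equivariance without bespoke indexing mathematics; the
backward pass is the corresponding scatter-add.

Weights are shared across output orientations, so a group layer has
exactly the parameter count of a plain 3D convolution consuming the same
flattened input; biases are shared across orientations because
per-orientation biases would break equivariance.

Exactness caveats: max-pooling halves dimensions with window/stride 2, so
exact equivariance requires every intermediate grid dimension to be even;
test configurations use grids divisible by `2^stages`. On the clinical
192 x 192 x 50 grid the z-flip symmetry is only approximate after the
first pooling stage (50 is not divisible by 32); this mirrors the original
architecture's silence on the issue and is documented rather than hidden.

## Architectures

`encoder_config()` describes a five-stage encoder (per-stage: convolution,
instance normalization, ReLU, 2x2x2 max-pooling), global average pooling,
two fully connected ReLU layers with dropout between them, and a sigmoid
output. Setting `equivariant = FALSE` swaps every group layer for a plain
convolution with the identical configuration — that flag is the *only*
difference between the baseline CNN and the G-CNN, mirroring the paired
comparison in the underlying study design.

Three variants share this encoder:

* `build_classifier()` — supervised onset classification;
* `build_cae()` — a convolutional autoencoder (1x1x1 bottleneck
  convolution plus a mirrored decoder of nearest-neighbour upsampling and
  convolution) for unsupervised pre-training on labeled + unlabeled
  cohorts; its encoder weights transfer via `encoder_checkpoint()`;
* `build_ae_regularized()` — one encoder with both heads, trained on the
  aggregated loss `L = alpha * L_bce + (1 - alpha) * L_mse`.

Design choices in places the source architecture leaves open:

* **Channel widths** (default 8, 16, 32, 64, 128, times a width factor),
  fully connected widths, dropout rate and bottleneck width are
  configuration, not constants, because the original hyperparameters are
  not published.
* **Instance normalization** after each encoder convolution (default on).
  The discriminative FLAIR-conspicuity signal is a sub-percent
  perturbation of a dominant background component; without normalization,
  gradient descent at desk scale collapses to the majority logit (training
  loss pinned at ln 2). Per-sample, per-channel standardization over space
  removes the background mode, and it preserves equivariance *exactly*:
  spatial permutations leave channel statistics unchanged, and
  orientation-channel permutations carry the statistics along.
* **Decoder upsampling** is nearest-neighbour + convolution (avoids
  checkerboard artifacts), with per-stage target shapes recorded from the
  encoder so odd dimensions reconstruct to the exact input shape.
* **Dropout placement**: between the two fully connected layers.
* **Orientation pooling happens once, before GAP**, keeping oriented
  features through all stages (the alternative — pooling per stage — loses
  orientation information early).
* The classifier attributes and thresholds operate on the sigmoid score;
  binary calls use the convention `score >= threshold` = class 1 (onset
  within 4.5 h).

## Training

Stochastic gradient descent with Nesterov momentum (defaults: learning
rate 0.01, momentum 0.9) minimizes class-weighted binary cross-entropy
with weights `w_c = N_total / (2 N_c)`, which balances the weighted class
masses exactly (`w0 N0 = w1 N1`). Autoencoder variants use mean squared
reconstruction error, aggregated as `alpha * L_bce + (1 - alpha) * L_mse`
with `alpha` defaulting to 0.5 for the regularized model. The best
checkpoint is selected by validation loss with optional early-stopping
patience. One master seed fans out to splitting, initialization, shuffling
and dropout, so runs are bit-reproducible under single-threaded execution.

Cross-validation uses 4 folds with train/validation/test ratios
56 % / 19 % / 25 %, floor rounding and the remainder assigned to training:
a 489-patient cohort yields four disjoint 122-patient test folds. The
splits are made once and reused by every model; test scores are computed
only after training finalizes, and intensity standardization statistics
are fitted on training data only (the `apply_standardizer()` interface
takes explicit statistics, so validation/test leakage is impossible by
construction).

## The synthetic cohort

The generator (`phantom_config()`, `generate_cohort()`) is a statistical
stand-in, not a biophysical simulator. Each phantom is an ellipsoidal
"brain" with smoothed-Gaussian-field texture and ventricle-like dark
structures, in which:

* every labeled patient carries an ellipsoidal lesion with DWI contrast
  1.2 (far above the 0.08 noise floor — always visible);
* the same lesion's FLAIR contrast is
  `flair_contrast_max * plogis((t - 4.5) / 1.5)` for onset-to-imaging time
  `t`, i.e. monotone in lesion age with its midpoint at the decision
  boundary, making the boundary region the hardest — as in the clinic;
* onset times are drawn so that 43.35 % of labeled patients are in the
  early class (the prevalence of the cohort the package emulates), uniform
  within each side of the 4.5 h boundary on [0.5, 24] h;
* confounders occur independently of onset time: periventricular
  leukoaraiosis-like FLAIR hyperintensity (rate 0.3), old FLAIR-bright
  lesions (0.2), and focal DWI-bright susceptibility-like artifacts (0.1);
* each patient is given a random one of the 16 grid orientations,
  emulating arbitrary positioning and laterality;
* the unlabeled pre-training cohort is distribution-shifted: 35 %
  lesion-free, a quarter of lesions in the lowest slices (the stand-in for
  infratentorial strokes), onset time unknown for 37 %.

Because the confounders dominate *global* intensity statistics (a logistic
model on global channel means performs at chance), classifying a phantom
requires detecting FLAIR signal specifically at the DWI-identified lesion
— the same co-location reasoning a human rater applies. A hand-crafted
co-location feature achieves AUC ~0.93-0.97 across working resolutions,
which bounds what a perfect model could do and confirms the information
survives downsampling.

What the phantoms do **not** model: realistic anatomy, b-value physics,
hemorrhage, motion, scanner effects, or deformable misregistration
(volumes are generated coregistered; the rigid-resample backend exists for
real data). Passing tests on phantoms therefore demonstrates the
correctness of the machinery and the learnability of the mismatch signal,
not clinical performance.

Synthetic raters (`rater_model()`, `generate_raters()`) rate each patient
mismatch / no-mismatch with configurable sensitivity and specificity
against the true label, and mark a configurable fraction indeterminable,
biased toward low-FLAIR-contrast cases where real raters struggle.

## Evaluation

All metrics follow the clinical workflow: AUC via the Mann-Whitney rank
formula (ties 1/2); binary calls at two operating points — the Youden
threshold (maximizing sensitivity + specificity − 1 over all candidate
thresholds: midpoints of sorted unique scores plus sentinels) and a
*sensitivity-calibrated* threshold, the largest threshold whose validation
sensitivity reaches the human multicenter benchmark of 0.62, frozen and
applied to test predictions. Indeterminable ratings count as the late
class (such patients would be excluded from thrombolysis);
`augment_ratings()` substitutes the model's call exactly where a rater was
indeterminable. Interrater agreement is Cohen's kappa on the binary calls
(a three-category mode is provided since the original treatment of
indeterminables in kappa is not documented). Significance of paired rating
schemes uses a bootstrap of N = 200 patients per draw, with the number of
repetitions doubled until the mean bootstrap metric is within 0.01 of the
full-cohort value, followed by a two-sided Wilcoxon signed-rank test on
the paired metric values (zero differences dropped; exact null for <= 25
untied pairs, normal approximation with tie correction otherwise;
significance at p < 0.05).

## Explanations

`smoothgrad()` averages absolute input gradients over `n = 25` noisy
replicates (noise sd = 0.1 x intensity range, the usual SmoothGrad
setting). The *pre-sigmoid logit* is attributed rather than the
probability, avoiding vanishing gradients at saturated outputs. Heatmaps
are max-normalized per volume and thresholded at one universal value so
patients are comparable; on phantoms, `localization_score()` replaces
visual rating with lesion coverage and Dice, flagging a case
well-localized when coverage exceeds 0.5 on both channels — a documented
surrogate for, not a reproduction of, human heatmap rating.

## Numerical choices and problem sizes

* Double precision throughout; equivariance holds to ~1e-14 and the test
  tolerances (1e-5 layers, 1e-4 end to end) are deliberately loose.
* Convolutions run through an im2col + BLAS matrix-multiply path at
  training sizes, with a direct-loop C++ fallback above a 300 MB per-layer
  threshold (e.g. the 192 x 192 x 50 grid).
* Scores are clamped to `[1e-7, 1 - 1e-7]` inside the cross-entropy.
* Degenerate inputs are rejected with explicit messages: non-square
  in-plane grids for equivariant models, even kernels (no rotation
  center), single-class label vectors, zero-variance standardization.
* The test suite trains at deliberately small problem sizes chosen as the
  package's own desk-scale study: the end-to-end comparison uses 200
  phantoms generated at 64 x 64 x 32 and resized by the preprocessing
  module to a 16 x 16 x 8 working grid, 150/50 train/validation, a
  two-stage G-CNN with channels (2, 4), 40 epochs of SGD (lr 0.01, batch
  8), three seeds per arm. Under these conditions the G-CNN reaches
  validation AUC well above 0.85 while the matched plain CNN, facing
  randomly oriented patients without built-in symmetry, does not beat it.

## Known limitations

* No GPU or batch-parallel execution; the engine is single-threaded R/C++
  with BLAS, intended for desk-scale studies and testing, not
  192-resolution training.
* Exact invariance requires even intermediate grids; the clinical grid is
  only approximately z-flip-equivariant beyond stage 1.
* The CAE decoder reconstructs through a heavily compressed bottleneck;
  at very small grids reconstruction quality is limited (the pre-training
  pathway is exercised and tested for contract correctness, not tuned for
  reconstruction fidelity).
* Synthetic-rater and phantom parameters are statistical conveniences;
  none of the clinical performance numbers of the emulated study can be
  reproduced from synthetic data, and the package does not attempt to.
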