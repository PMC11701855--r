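---
title: "Decorrelative ensembles for robust ECG classification: models, attacks, and uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decorrelative ensembles for robust ECG classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decorrens)
```

## The problem

Deep classifiers for electrocardiograms are brittle in two related ways: a
tiny, targeted perturbation of the waveform — far below what a human reader
would notice — can flip the prediction, and the model gives no usable signal
that anything went wrong. In a clinical triage setting both failures matter:
a model should be hard to fool, and when it *is* fooled (or simply out of
its depth) it should know it, so the case can be routed to a human.

`decorrens` implements a deep-ensemble answer to both demands. An ensemble
of `K` classifiers averages its members' class-probability outputs; the
spread among the members doubles as an epistemic uncertainty signal. The
package provides two training mechanisms that push members toward
*different* features — linear feature decorrelation and Fourier-domain
input partitioning — plus two gradient-based hardening methods (ensemble
adversarial training and DVERGE-style feature distillation), white-box
attacks to measure robustness, and the evaluation stack that turns
per-record uncertainties into decision-quality metrics.

Everything runs end-to-end on synthetic ECG-like signals, so the full
pipeline is exercisable — and testable — on a laptop without any data
download.

## Ensemble inference and mutual-information uncertainty

An ensemble prediction is the arithmetic mean of member probability
outputs,

$$\hat{y} = f_{\mathrm{ens}}(x) = \frac{1}{K}\sum_{k=1}^{K} f_k(x),$$

itself a distribution over the `C` classes. The epistemic uncertainty of a
sample is the mutual information between the predicted label and the model
parameters, estimated from the ensemble as

$$I = H\!\left(\tfrac{1}{K}\textstyle\sum_k f_k(x)\right)
      - \tfrac{1}{K}\textstyle\sum_k H(f_k(x)),$$

the entropy of the mean prediction minus the mean of member entropies
(natural log; `mutual_information()`). `I` is zero exactly when all members
agree and bounded by `log C`; it is large when individually confident
members disagree — the signature of an input outside the ensemble's shared
competence.

Raw `I` has no absolute scale, so it is normalized by the extreme values
observed on the training set: `I_norm = (I - I_min) / (I_max - I_min)`
(`calibrate_bounds()`, `normalize_uncertainty()`). Test samples can fall
outside the training range, so `I_norm` is deliberately **not** clamped to
`[0, 1]`. The bounds are computed post hoc over the full training set with
the final weights: the during-training alternative depends on the exact
schedule of snapshots, while the post-hoc scan is deterministic and
reproducible.

## The classifier

No deep-learning runtime is assumed: the package ships a compact, fully
configurable 1D convolutional network with hand-written forward and
backward passes over BLAS matrix operations. The architecture is
`[conv → batch norm → ReLU] × B`, global average pooling over time, a dense
penultimate layer of `D` units (default `D = 64`), and a linear map to `C`
logits with softmax. Three design points matter downstream:

* the penultimate layer is the feature matrix `Z` that decorrelation
  operates on. Features are taken **post-activation** by default — the
  location "just before the final linear layer" names a position, and the
  rectified values are what that layer actually consumes — with the
  pre-activation values available via `extract_features(..., activation =
  "pre")`;
* batch-norm layers are enumerable by name (`model_layer_pool()`), giving
  DVERGE its sampling pool;
* all prediction and feature extraction run in evaluation mode (running
  batch-norm statistics), so outputs are deterministic in the weights and
  input. Cached features for decorrelation are likewise extracted in
  evaluation mode.

Every gradient the package needs — with respect to parameters (training),
to the input (attacks), and to the input of an intermediate-layer objective
(DVERGE) — is computed analytically by the same backward pass and is
finite-difference-tested in the suite. Conv biases are omitted when batch
norm is enabled (the normalization absorbs them). Adam is the optimizer,
with the conventional defaults and learning rate `1e-3`.

## Feature decorrelation

Two networks have redundant representations when one's features are
linearly predictable from the other's. For feature matrices
$Z_1, Z_2 \in \mathbb{R}^{N \times D}$, regress $Z_2$ on $[Z_1, 1]$ by
ordinary least squares and form the residual sum of squares
$SS_{res}$ and the total sum of squares
$SS_{tot} = \lVert Z_2 - \bar{Z}_2 \rVert^2$ (column-wise means). The
decorrelation loss is

$$L_R(Z_1, Z_2) = \log(SS_{tot} + \epsilon) - \log(SS_{res} + \epsilon),$$

with `eps = 1e-5` for stability. With `eps = 0` this satisfies
$e^{-L_R} = SS_{res}/SS_{tot} = 1 - R^2$, so minimizing `L_R` minimizes the
multivariate coefficient of determination between the two feature sets. The
implementation solves the regression with a pivoted QR factorization —
never an explicit pseudo-inverse — which is numerically stable and falls
back to the minimum-norm solution on rank-deficient regressors instead of
erroring. Gradients come from the envelope theorem: at the least-squares
optimum, $\partial SS_{res}/\partial Z_1 = -2\,\hat{R}\hat{\beta}^\top$
with $\hat R$ the residual matrix.

Two modifications make the loss practical at realistic batch sizes and
ensemble sizes (`randomized_lr_loss()`):

1. **Random projections.** The regression needs `N > D + 1` to be
   overdetermined; with `D = 64` and batches of 64 it is not. The regressor
   (intercept appended) is therefore compressed to `r` dimensions
   (default `r = 32`) by a projection with i.i.d. `N(0, 1/D)` entries drawn
   *fresh for every batch and every prior model*, so that over training no
   fixed subspace can stay correlated unnoticed.
2. **Role swapping.** Regression is asymmetric; a fair coin decides per
   call which feature set acts as regressor and which as regressand.

Scaling to `K > 2` members is sequential: model 0 trains plainly; after
each model finishes, its features on all training records are cached to
disk keyed by record id (`build_feature_cache()`); model `k` then minimizes

$$L_{total} = L_{ce} + \frac{\lambda}{k}\sum_{i=0}^{k-1}
  L_R^{*}(Z_k, Z_i),$$

with `lambda = 0.2`, the cached features entering as constants — gradients
flow only through the live model's features. This avoids holding `K`
networks in memory and lets decorrelation compose freely with the other
training flags.

Numerical corner case: a trailing mini-batch smaller than `r + 1` makes the
projected regression underdetermined; the decorrelation term is skipped for
that batch and the skip is counted in the loss trace.

Where a design point was genuinely open, the package decides and documents:
the swap coin and projection are drawn *per prior model* within a batch
(fresh randomness for each pairing, matching the per-prior placement of the
draws in the sequential training step), and cached features are extracted
in evaluation mode.

## Fourier partitioning

The second diversification mechanism assigns ensemble members different
frequency views of the same input. A bank of "ring" filters —
nonnegative, zero-phase frequency responses with raised-cosine crossfades
that sum to exactly 1 at every bin (`design_ring_filters()`) — splits the
spectrum; member 0 sees the raw input and member `j ≥ 1` sees the input
multiplied by response `j` in the Fourier domain. The transforms apply
identically during training, inference, and **inside attack gradients**:
the filters are linear and self-adjoint (real, even responses), so the
pullback of a gradient through a filter is the same filter applied to the
gradient — a property the test suite checks by finite differences.

The published frequency responses for this scheme are shown only
graphically in the source literature, so the cutoffs are configuration
parameters. The default for `K = 3` is a single edge at `fs / 8` with a
rolloff of `fs / 50`: on the synthetic data this separates the two groups
of class-discriminative tones (below) while leaving both members enough
rhythm information to train on. Exact complementarity gives perfect
reconstruction, `h1(x) + h2(x) = x`, which the suite asserts to `1e-6`.

## Attacks

**PGD.** The standard white-box $\ell_\infty$ attack: iterate
$x'_{i} = \mathrm{Clip}_{\epsilon}\!\left(x'_{i-1} +
\alpha\,\mathrm{sign}(\nabla_x L)\right)$, projecting after every step
first onto the $\epsilon$-ball around the clean input and then onto the
signal domain bounds (the clip in the usual formulation merges both; the
order here is stated explicitly). Defaults: 20 steps, `alpha = epsilon/10`,
`sign(0) = 0`.

**Ensemble targeting.** Backpropagating through all `K` members at every
step is wasteful; because `-log` is convex, Jensen's inequality bounds the
ensemble cross-entropy by the mean of member cross-entropies, and that
surrogate is optimized by simply rotating the targeted member,
`k = i mod K` (`alternating_target_schedule()`). Both this mode and
single-model targeting (default target: the first-trained member) are
implemented, since published robustness protocols use each in different
places.

**SAP.** Smooth adversarial perturbations adapt PGD to ECG by optimizing a
latent perturbation field `theta` whose effect on the input is the average
of its convolutions with `M` Gaussian kernels
(widths `s`, standard deviations `sigma`; `build_kernel_bank()` ships the
published banks for both challenge datasets). Gradients are taken with
respect to `theta` *through* the smoothing, so the optimized perturbation
cannot carry the square-wave artifacts that betray plain PGD on
physiological signals. Implementation choices: `theta` starts at zero
(making the `epsilon = 0` and zero-step cases exact identities), the
convolutions use reflect padding (no spike artifacts at record edges), and
both the smoothing and its exact adjoint are one precomputed sparse matrix
product. Kernels are nonnegative and sum-normalized, so
`max|theta| <= epsilon` implies the smoothed perturbation obeys the same
bound; ball containment is asserted on every call.

## Hardening

**Ensemble adversarial training** (`harden_ensemble_adversarial()`)
re-trains each naturally trained member, one after another, on mini-batches
perturbed by PGD targeting that member. The published budget for this phase
is wall-clock time; the package uses an epoch budget instead
(`budget_epochs`) so results are portable across hardware — the deliberate
divergence is this paragraph.

**DVERGE** (`dverge_training_round()`) diversifies members' *vulnerabilities*
rather than their features: a sample `x`'s non-robust features at a random
post-batch-norm layer of member `i` are distilled onto a carrier sample
`xs` within an `epsilon`-ball (`dverge_distill_sample()`, inner projected
signed-gradient descent, step size `epsilon/10`, default 10–20 steps), and
all *other* members train on the distilled inputs with the carrier's label.
With few classes a randomly drawn pair often shares a class, which makes
the distillation vacuous; pairs are therefore constrained to `y != ys`,
resampling within the epoch when a draw collides. The inner step count for
both hardening methods is configurable (default matching the 20-step attack
convention, since the source procedure leaves it unstated).

## Evaluation

A threshold `I_T` splits inferences into certain (`I_norm <= I_T`) and
uncertain. Three measures follow (`threshold_metrics()`):

* `Rcc` — P(correct | certain),
* `Riu` — P(uncertain | incorrect),
* `UA`  — P(correct ∧ certain ∨ incorrect ∧ uncertain),

each swept over an even grid of 201 thresholds on `[0, 1]` and integrated
by the trapezoidal rule into an AUC (`curve_and_auc()`; the integration
rule is unstated in the source, trapezoid is the package's choice, and the
refinement test pins self-consistency). Empty denominators — no certain
records, or no incorrect records — return 1.0, vacuous truth, and are
flagged; flagged values are included in the AUC, which keeps the AUC of a
perfect model defined (and equal to 1). Out-of-range `I_norm` values
participate in thresholding as-is, consistent with the non-clamping above.

`delta_uncertainty()` reports `E[I_norm | incorrect] - E[I_norm |
correct]`; a strong attack can leave no correct predictions, in which case
the one-sided mean is returned with a flag rather than `NaN` — mirroring
how the measure degrades on heavily attacked data.

`build_mixed_dataset()` composes the partially attacked dataset for triage
analysis (default: 50% clean, 25%/15%/10% at three rising magnitudes;
largest-remainder rounding makes the stratum sizes exact).
`deferral_curve()` then orders inferences from most to least confident
(ties broken by record id, for determinism) and asks: if the `q` most
confident cases take the model's answer and the rest go to a human (counted
correct), what fraction of all cases is misclassified? Lower curves — and
lower AUCs — are better.

## The synthetic data generator

`generate_dataset()` produces the labeled fixture every other module runs
on. It emulates exactly the statistical structure the methods assume of
single-lead ECG, and nothing more:

* **rhythm**: beats are placed by per-interval draws around a class mean;
  the `afib_like` class has a large interval jitter (and no P bump, plus a
  4–9 Hz baseline oscillation standing in for fibrillatory waves), `normal`
  and `other` are regular;
* **morphology**: each beat is a difference-of-Gaussians QRS complex with
  Gaussian P and T bumps; `other` widens the QRS 2.2-fold; `noise` is
  band-limited noise with no pulse train;
* **band-separable class content**: every class carries a weak narrowband
  tone, classes 0 and 2 below the `band_split` frequency (default `fs/8`,
  matching the default partition edge) and classes 1 and 3 above it — this
  is what gives the partitioned members genuinely different discriminative
  information;
* **normalization**: records are zero-padded/truncated to fixed length
  first, then max-abs scaled per record into `[-1, 1]`, the preprocessing
  order used for the real challenge recordings.

All waveform constants are package inventions chosen once for visual
ECG-likeness. The generator is deterministic: one config seed produces
bit-identical arrays.

What passing tests on this fixture do and do not show: they demonstrate
that the training objectives, attacks and metrics behave as specified —
decorrelation lowers measurable cross-model feature correlation, partition
members provably depend on their own band, attacks degrade accuracy and the
uncertainty stack separates wrong from right. They do **not** show
clinical-grade arrhythmia discrimination; the generator has no
physiological dynamics, no inter-patient variability, no electrode
artifacts, and its classes are cleanly separable by construction. Real-data
conclusions require the real recordings (the preprocessing surface —
`pad_truncate_normalize()` with a pluggable amplitude-scaling hook — is the
adapter point).

## Problem sizes and reproducibility

The desk-scale study conditions used by the test suite and the acceptance
script are: 250 records per class (1,000 total, 90/10 train/validation
split), 100 Hz sampling, 10-second records, `K = 3` members of the default
architecture trained 10 epochs with batch size 64, ensemble-alternating
PGD at `epsilon = 0.1` (amplitude units on the `[-1, 1]` scale, the
mid-range of published attack magnitudes for amplitude-normalized
recordings) with 20 steps. Stochastic claims (decorrelation lowers feature
correlation; the dec + part ensemble separates incorrect from correct
better under attack) are evaluated over three seeds with a majority
criterion, reflecting run-to-run training variance at this scale.

Every random draw in a pipeline run derives from the single config seed
through fixed integer streams: data generation, the train/validation split,
weight initialization, batch shuffling, decorrelation coins and
projections, hardening pairings and layers, and mixed-dataset assignment.
Identical config + seed reruns produce bit-identical manifests, scores and
reports on one device; the manifest records the config hash and per-member
weight hashes so this can be verified cheaply.

## Known limitations

* The classifier is a compact CNN, not a replication of any published ECG
  architecture; it preserves the structural contract the methods need (a
  `D`-unit penultimate layer, enumerable batch-norm layers) at a size that
  trains in seconds on a CPU.
* Training is single-device and single-threaded beyond BLAS; there is no
  GPU path.
* The MATLAB-format readers for the public challenge datasets are not
  bundled; adapters reduce to building a `signal_batch` from any array
  source plus the provided pad/truncate/normalize step.
* Attack scope is white-box PGD and SAP; black-box and transfer protocols
  are out of scope.
* `I_norm` calibration uses training-set extremes; under distribution shift
  the normalization remains well-defined but its `[0, 1]` anchor points
  lose their interpretation — by design, values outside `[0, 1]` are
  reported as-is.
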