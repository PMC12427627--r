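---
title: "An interpretable multimodal pipeline for ASD classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An interpretable multimodal pipeline for ASD classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`asdfuse` implements a four-stage classification pipeline for Autism
Spectrum Disorder (ASD) that fuses two very different kinds of evidence: a
tabular behavioral phenotype (clinical scores, IQ measures, demographics)
and a structural MRI volume. The design goal is that every stage stays
inspectable: the behavioral model is additive and decomposable by
construction, the imaging model reduces to region-level graph features over
a named atlas, and the final classifier's weights are themselves an output
that can be examined per subject.

This vignette describes the model, the choices we made where the design was
genuinely open, what the synthetic cohort generator does and does not
emulate, and the numerical conventions used throughout.

## The model

### Behavioral branch: an additive network with selected interactions

Each preprocessed behavioral feature $x_i \in [0,1]$ is passed through its
own small subnetwork $f_i$, and a screened set $L$ of feature pairs through
bivariate subnetworks $f_{ij}$. The predicted ASD probability for a subject
with features $x$ is

$$\hat y \;=\; \sigma\!\Big(\sum_i f_i(x_i) \;+\; \sum_{(i,j)\in L} f_{ij}(x_i, x_j) \;+\; b\Big),$$

with $\sigma$ the logistic link. The link is required for consistency: the
output is a probability trained with binary cross-entropy, while the body
of the model is a raw sum of effects. Each subnetwork has two hidden ReLU
layers (width 16; depth is the modelling commitment, width is a capacity
knob that mattered little in our experiments).

The fit proceeds in three stages:

1. **Main effects.** All univariate subnetworks, per-effect output scales
   $\gamma_i$, and the bias are trained jointly with binary cross-entropy,
   Adam (learning rate $10^{-3}$), 30 epochs, minibatches of 64. An L1
   penalty ($10^{-4}$) on the $\gamma_i$ encourages unused effects toward
   zero.
2. **Interaction screening.** For every candidate pair $(i,j)$ a shallow
   regression tree (depth 2) is fitted to the residuals of the main-effects
   model on $(x_i, x_j)$; pairs are ranked by residual variance explained
   and the top $k$ (default 10) are kept, ties broken lexicographically so
   the selection is deterministic.
3. **Interaction effects.** Bivariate subnetworks for the selected pairs
   are trained on top of the frozen main effects, same schedule.

After training, each effect's output is mean-centered over the training set
with the means absorbed into $b$. Centering is an identifiability choice:
without it, constant offsets can shuttle freely between effects and the
bias, making importance scores and partial-dependence curves arbitrary.
Effects whose contribution variance falls below $10^{-4}$ of the total are
pruned and contribute exactly zero thereafter.

Interpretability then comes for free rather than post hoc:
`gami_effects()` returns the exact per-subject decomposition (its row sums
plus the bias reproduce the prediction through the link to machine
precision), `gami_importance()` ranks effects by normalized contribution
variance, and `gami_partial_dependence()` evaluates a univariate effect on
a grid — no data averaging is needed because the model is additive by
construction.

Two honest caveats from our synthetic experiments. First, when main
effects are underfitted (the fixed 30-epoch schedule is short), residual
screening will happily select pairs of *individually* informative features
and the interaction subnetworks absorb part of the main-effect signal; the
effect ranking then names the right features but sometimes through
interaction terms. `gami_top_features()` collapses the effect ranking to
feature level for exactly this reason. Second, under pure-noise labels the
contribution variances of fitted effects are far from uniform, so a
relative variance threshold prunes nothing; the meaningful null guarantee
is distributional (cross-validated AUC near 0.5), which the test suite
checks, not a flat importance profile.

### Imaging branch: convolutional features pooled onto an atlas graph

Volumes are encoded in four steps:

1. Two 3×3×3 convolution blocks (8 then 16 channels, stride 1, zero
   padding, ReLU). Padding preserves the spatial grid — necessary because
   the atlas mask is applied *after* convolution.
2. Feature maps are mean-pooled inside each atlas region, giving one node
   per region (nodes ordered by ascending atlas label). Pooling raw
   intensities instead of convolutional features is available as a config
   fallback (`pool_input = "raw"`).
3. Two graph-convolution layers $H \leftarrow \mathrm{ReLU}(\hat A H W)$
   with the symmetric-normalized propagation operator
   $\hat A = D^{-1/2}(A + I)D^{-1/2}$, where $A$ is the region adjacency:
   $A_{ij} = 1$ iff some voxel of region $i$ shares a face (6-connectivity)
   with a voxel of region $j$. Face adjacency is the strictest contiguity
   notion on a voxel grid and gives a deterministic, closed-form graph for
   the toy atlases used in testing.
4. The node embeddings are flattened (fixed node order makes this
   well-defined) and mapped linearly to a `embed_dim`-length vector
   (default 128).

The encoder is trained end-to-end with a temporary linear head and binary
cross-entropy (Adam, $10^{-3}$, 30 epochs); the head is discarded. Dropout
(rate 0.2) is applied to the flattened node embeddings during training.
Minibatches default to 16 subjects — a memory choice: the im2col patch
matrix for a 16³ volume at 8 input channels is ~113 MB per 16 subjects, and
all convolution work is done as stacked BLAS products over the batch.

### Fusion: a 129 → 64 → 32 autoencoder

The behavioral branch contributes a single scalar (the ASD probability) and
the imaging branch a 128-dimensional vector. The concatenated input is
compressed 129 → 64 → 32 by a ReLU encoder and reconstructed by a mirrored
decoder (linear output layer, since standardized inputs are unbounded),
trained on mean squared error (Adam, $10^{-3}$, 30 epochs, batches of 64).
Inputs are standardized with training-split z-scores first; without this
the wide MRI block dominates the reconstruction objective and the
1-dimensional behavioral scalar is essentially ignored. The 1-vs-128
asymmetry is itself a design tension: an optional `behavioral_vector` flag
appends the per-feature effect contributions to the scalar for a richer
behavioral block, but the scalar is the default.

### Classifier: hypernetwork-generated per-subject weights

A shared network $H$ (one hidden ReLU layer of width 64, linear head) maps
each subject's 32-d latent $z$ to the full parameter set of that subject's
own classifier:

$$\theta = (W_1 \in \mathbb{R}^{16\times32},\; b_1 \in \mathbb{R}^{16},\;
W_2 \in \mathbb{R}^{2\times16},\; b_2 \in \mathbb{R}^2), \qquad
\hat y = \mathrm{softmax}(W_2\,\mathrm{ReLU}(W_1 z + b_1) + b_2),$$

562 generated scalars per subject. Personalization comes only from $z$: the
same latent always generates the same classifier. Training minimizes
two-class cross-entropy over all subjects in a single full batch (30
epochs, Adam, $10^{-3}$). The generator head is initialized at scale
$10^{-2}$ so initial parameters are near zero and initial predictions near
(0.5, 0.5); exact probability ties at prediction time resolve to Control.

One property worth knowing: because the subject's latent enters the forward
pass twice (as the classifier input *and* through the generated weights),
the effective model is multiplicative in the shared parameters and trains
very fast — it can memorize randomly labelled training sets within the 30
full-batch steps. In-sample loss is therefore not a meaningful null
diagnostic for this stage; held-out label accuracy is, and that is what the
test suite checks.

The `no_hypernetwork` ablation arm replaces $H$ with one shared
$(W_1, b_1, W_2, b_2)$ of identical geometry, trained on the same schedule,
with the same small-scale output initialization — a short full-batch
schedule from a conventional random output layer leaves a fixed MLP at
chance, which would make the comparison against the hypernetwork unfair
for the wrong reason.

## Preprocessing and leakage

`fit_preprocessor()` computes per-column medians (numeric), modes and
alphabetical label maps (categorical), and post-imputation min/max bounds;
`apply_preprocessor()` replays them. Scaling maps onto $[0,1]$ with three
conventions for cases the fitted bounds cannot anticipate: constant columns
map to 0, out-of-range values are clipped, and unseen categorical levels
receive a reserved code (the map size) rather than an error — robustness
for cross-site tables. The diagnosis column is coded 1 = Control, 2 = ASD
on disk and 0/1 internally, ASD positive.

All statistics are computed from whatever table the fit function is given;
`run_pipeline()` and `run_ablation()` pass only the training split, so
cross-validation is honest end to end (every stage, including the fusion
standardization, is fitted on training subjects only). Subjects are aligned
across modalities by sorted-id intersection.

## The synthetic cohort generator

`generate_cohort()` produces the study conditions used by the tests and the
acceptance script: balanced classes; behavioral features drawn as standard
normals with the class-1 mean shifted by `behavioral_effect` in a chosen
subset of features; volumes drawn as unit-variance noise with the class-1
mean shifted by `roi_effect` inside a chosen subset of atlas regions;
missing behavioral cells completely at random. The toy atlas is a
deterministic grid partition, so region adjacency is known in closed form.
The generator's seed fully determines the cohort — regeneration is
bit-identical.

What this emulates is the *weakest sufficient* signal structure: pure mean
shifts with Gaussian noise. What it deliberately does not emulate: site or
scanner batch effects, realistic cortical anatomy, covariate structure
(age, sex), label noise, or heavy-tailed score distributions. Passing
tests on these cohorts therefore demonstrates that the machinery recovers
planted signal and stays calibrated under a true null — not that the
pipeline attains any particular accuracy on real clinical data.

Default evaluation scales, chosen as desk-scale study conditions: the
signal-recovery and null cohorts use n = 400 subjects, 20 behavioral
features (5 informative, effect 2.0), 16³ volumes over a 16-region atlas
(3 informative regions, effect 2.0); the ablation study uses n = 120
subjects, 6³ volumes and an 8-region atlas over 5-fold cross-validation
with 5 generator seeds.

## Numerical conventions

* **Metrics.** Accuracy, precision, recall, specificity and F1 follow
  their confusion-matrix closed forms with ASD (label 1) positive; ratios
  with zero denominators are reported as `NaN` with a warning, never
  silently zeroed. AUC uses the rank (Mann–Whitney) formulation with
  midranks for ties; the reported ROC curve integrates (trapezoids) to the
  same value to 1e-9.
* **Cross-validation.** Stratified folds preserve class proportions to
  within one subject; fold assignment is a seeded within-class shuffle.
* **Determinism.** Every stochastic step (initialization, batching,
  dropout, splits, permutations) runs under a seed derived from a single
  master seed; the caller's RNG state is saved and restored around each
  fit. Two runs with the same cohort and config produce identical reports.
* **Degenerate inputs.** Single-class label vectors, all-missing columns,
  empty modality intersections, shape mismatches and non-finite generated
  weights raise errors naming the offending quantity.

## Known limitations

* The fixed 30-epoch schedules (kept as stated study conditions) underfit
  the behavioral branch at small n; the importance ranking remains
  feature-accurate but can route credit through interaction terms.
* The hypernetwork's capacity makes in-sample metrics uninformative;
  always evaluate held out.
* The MRI encoder assumes volumes and atlas share a grid; no resampling or
  registration is performed.
* Single-site, single-modality-pair scope: no batch-effect handling, no
  functional imaging, no multi-class support.
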