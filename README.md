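# asdfuse

An interpretable multimodal classification pipeline for Autism Spectrum
Disorder (ASD), for researchers who want to combine a tabular behavioral
phenotype (ADOS/ADI-R-style clinical scores, IQ, demographics) with a
structural MRI volume without giving up the ability to inspect every stage.

The pipeline has four stages:

1. **Behavioral embedding** — a neural generalized additive model with
   selected pairwise interactions. Each feature `x_i` gets its own
   subnetwork `f_i`, screened pairs `(i, j)` get bivariate subnetworks
   `f_ij`, and the ASD probability is

   `ŷ = σ( Σ_i f_i(x_i) + Σ_(i,j)∈L f_ij(x_i, x_j) + b )`.

   The model is additive by construction, so per-subject effect
   contributions, variance-based importance rankings and exact
   partial-dependence curves come directly from the fitted terms.
2. **MRI embedding** — a hybrid CNN–GNN encoder: two 3×3×3 convolution
   blocks (shape-preserving), mean pooling of feature maps inside each
   atlas region, two graph-convolution layers over the anatomical-adjacency
   graph using the symmetric-normalized operator
   `Â = D^(−1/2)(A + I)D^(−1/2)`, and a linear readout to a 128-d vector.
3. **Fusion** — an autoencoder compressing the concatenated
   `[probability, MRI embedding]` input 129 → 64 → 32; the 32-d bottleneck
   is the fused latent `z`.
4. **Personalized classification** — a hypernetwork `H(z)` that generates
   each subject's own classifier weights
   `θ = (W1 ∈ R^{16×32}, b1, W2 ∈ R^{2×16}, b2)` (562 scalars), applied as
   `ŷ = softmax(W2 · ReLU(W1 · z + b1) + b2)`.

A synthetic multimodal cohort generator (class-shifted behavioral features
with missingness; volumes with intensity shifts inside chosen atlas
regions), leakage-safe preprocessing, metrics/ROC, stratified k-fold CV, a
five-variant ablation harness and permutation importance round out the
package. All networks are implemented in-package on base-R linear algebra
(with a small Rcpp kernel for 3D convolution patch extraction); no deep
learning framework is required.

## Worked example

```r
library(asdfuse)

cohort <- generate_cohort(n = 120, n_features = 10,
                          behavioral_effect = 2, n_informative_features = 3,
                          roi_effect = 2, informative_rois = 2,
                          shape = c(6, 6, 6), n_rois = 8,
                          missing_rate = 0.05, seed = 7)
result <- run_pipeline(cohort, pipeline_config(seed = 42))
result
#> Multimodal pipeline - held-out performance (n_test = 24)
#>   accuracy     1
#>   precision    1
#>   recall       1
#>   specificity  1
#>   f1           1
#>   auc          1
#>   n_correct    24
```

The planted signal (mean shift 2.0 in 3 of 10 behavioral features and in 2
of 8 atlas regions) is strong, and the held-out fifth of the cohort is
classified perfectly. The behavioral model explains *which* features drove
it:

```r
X <- apply_preprocessor(result$models$preprocessor, cohort$behavioral)
head(gami_importance(result$models$gami, X), 5)
#>            effect      score
#> 1 FEAT_02:FEAT_04 0.26923442
#> 2 FEAT_04:FEAT_06 0.21812763
#> 3         FEAT_08 0.18700724
#> 4 FEAT_02:FEAT_09 0.09266941
#> 5 FEAT_02:FEAT_06 0.04304068
cohort$truth$informative_features
#> [1]  2  4 10
```

Scores are normalized contribution variances (they sum to 1 over all
active effects). The two strongest effects involve the injected features 2
and 4 — at this small sample size part of the main-effect signal is
credited to interaction terms, which is why the ranking names pairs; see
the vignette for why, and `gami_top_features()` for the feature-level
collapse. `run_ablation(cohort, pipeline_config(seed = 42))` evaluates the
five pipeline variants (full, no autoencoder, no behavioral branch, no MRI
branch, fixed-weight classifier) under shared stratified 5-fold CV.

A thin command-line front end is installed at `inst/cli/asdfuse`
(`simulate`, `embed-mri`, `train`, `ablate`, `cv`).

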