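# factorgeom

Metrics and controls for asking how a neural population — or a deep
network layer — organises the variance driven by different visual scene
parameters (object identity, pose, background, lighting, camera viewpoint).
A code can *discard* a parameter's variance (**invariance**), keep it in a
subspace orthogonal to the variance of other parameters
(**factorization**), or entangle it with them.  The package is aimed at
computational and systems neuroscientists benchmarking population codes and
model representations.

## The quantities

With responses arranged as a conditions × features matrix, write
`var_p` for the total variance (trace of the feature-space covariance)
induced by varying parameter *p* around a base scene, averaged over base
scenes, and `var_all` for the total variance across all conditions.

* **Invariance**: `invariance_p = 1 − var_p / var_all`.
* **PCA-based factorization**: `factorization_p = 1 −
  var_{p | other-subspace} / var_p`, where the *other-parameter subspace* is
  the principal subspace (components up to 90% cumulative variance) of
  responses averaged over the levels of *p* — one vector per base scene —
  and the numerator repeats the variance computation after projection into
  that subspace.
* **Covariance-based factorization**: `1 − ⟨C_p, C_other⟩_F /
  (‖C_p‖_F ‖C_other‖_F)`, a threshold-free variant on the induced
  covariance matrices.  For rank-1 covariances at angle θ it equals
  `1 − cos²θ`.
* **Rotation lesion**: the change of basis `W = Σᵢ vᵢ^intra (vᵢ^inter)ᵀ`
  applied to class centers, `x → g + W(x_c − g) + (x − x_c)`, which
  destroys factorization of class from non-class variance while conserving
  every within-class statistic, the inter-center spectrum, and pairwise
  center distances.
* Supporting machinery: permutation shuffle nulls, stratified
  cross-validated linear decoders (SVM / multinomial logistic), ridge
  encoding fits, RDM (dot-product similarity) rank correlations, I1/I2
  behavioral signatures, and a metric-vs-predictivity meta-analysis over
  model-layer tables.

Synthetic-data generators plant all of this structure with known ground
truth (subspace alignments, latent variances, class geometry, movie-like
local/global structure, fabricated model zoos), so every estimator is
validated by parameter recovery.

## Worked example

Generate the canonical augmentation design — 100 base scenes × 4 scene
parameters × 10 levels (4000 conditions) — with all pairwise subspace
alignments set to 0.5, then score it:

```r
library(factorgeom)
dat <- gen_augmentation_responses(augmentation_sim_config(
  params = default_sim_params(alignment = 0.5), seed = 1))
geometry_scores(dat$responses, dat$design)
#> Population geometry scores (threshold 0.9 )
#>             param factorization_pca factorization_cov invariance
#>        background            0.9931            0.9101     0.5300
#>          lighting            0.9927            0.9119     0.5335
#>       object_pose            0.9925            0.9148     0.5107
#>  camera_viewpoint            0.9934            0.9110     0.5138
#> dimensionality: pc_count = 20, participation ratio = 15.69

ground_truth_factorization(dat$ground_truth, "background")
#> [1] 0.9174
```

The covariance-based scores (~0.91) recover the planted ground truth
(0.9174) to within sampling error; the PCA-based scores are near 1 because
each parameter's variance is nearly orthogonal to the base-scene subspace
that dominates the scene averages; invariance ≈ 0.53 reflects each
parameter contributing about one part in four of the within-design variance
plus the shared base-scene variance.

The lesion experiment on a class-structured population:

```r
cls <- gen_class_dataset(8, 25, 30, within_cov_spec = rep(1, 10),
                         center_alignment = 0, seed = 2)
les <- rotation_lesion(cls$responses, cls$design)
factorization_pca(cls$responses, cls$design, "class")  # 0.927
factorization_pca(les, cls$design, "class")            # 0.000
cv_decode(cls$responses, cls$design$class_label,
          regularization_grid = 1, seed = 1)$accuracy  # 0.935
cv_decode(les, cls$design$class_label,
          regularization_grid = 1, seed = 1)$accuracy  # 0.710
```

Rotating the class centers into the within-class subspace wipes out
factorization (0.93 → 0.00) and costs the decoder 22 points of accuracy,
while every within-class statistic is conserved to machine precision.

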