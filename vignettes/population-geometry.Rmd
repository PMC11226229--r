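---
title: "Measuring factorization and invariance in population codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring factorization and invariance in population codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(factorgeom)
```

## The problem

A visual population code — biological or artificial — must carry information
about many scene parameters at once: object identity, object pose, lighting,
background, camera viewpoint.  Two qualitatively different strategies can
keep object identity linearly decodable.  The code can *discard* nuisance
variance (invariance, or tolerance), or it can *segregate* it: keep the
variance driven by each parameter in its own subspace of population activity
space, orthogonal to the subspaces used by the others.  We call the second
strategy factorization.  Unlike invariance, factorization lets a single
population simultaneously support read-out of many parameters.  This package
implements the metrics that separate the two strategies, the controls that
validate them, and the downstream analyses (decoding, encoding fits, RDM and
behavioral-signature comparisons, metric-vs-predictivity meta-analysis) that
connect them to data.

## The metrics

All analyses view activity as a conditions × features matrix
(`response_matrix`).  "Variance" always means total variance: the trace of
the feature-space covariance, i.e. mean squared deviation from the centroid
summed over features, with the population (n) denominator.  Ratios of such
variances are denominator-convention-free, but a single convention is used
everywhere for consistency.

**Parameter-induced variance.**  In an augmentation design (each condition
renders one base scene with exactly one parameter varied),
`param_variance()` computes the total variance of each base scene's level
responses and averages over base scenes.  The total variance across all
conditions is `all_param_variance()`.

**Invariance.**  `invariance = 1 - var_param / var_all`.  A parameter that
barely moves the population scores near 1.

**PCA-based factorization.**  Averaging a base scene's responses over the
levels of the parameter of interest washes out that parameter's variance;
PCA on the resulting one-vector-per-scene set, truncated at a cumulative
explained-variance threshold (default 0.9), yields the *other-parameter
subspace*.  Factorization is the fraction of the parameter's variance that
avoids it: `1 - var_param_in_subspace / var_param`, with the projection
taken affinely about the subspace centroid.  Projections never increase
variance, so the score lives in [0, 1].

**Covariance-based factorization.**  A threshold-free alternative: one minus
the normalized Frobenius inner product of the covariance induced by the
parameter and the covariance induced (in the same per-scene fashion, pooled)
by all other parameters.  By Cauchy–Schwarz and positive semi-definiteness
this also lives in [0, 1].  For two rank-1 covariances along unit axes at
angle θ the score is exactly `1 - cos²θ` — the closed form the test suite
exploits.

**Grouped mode.**  Neural recordings rarely come with an augmentation
design; identity and nuisance vary jointly.  A grouped-mode design carries
only class labels, and the pseudo-parameters `"class"` (variance of class
centers) and `"non_class"` (mean within-class variance) play the roles of
the two variance sources.  The other-parameter subspace for `"class"` is the
principal subspace of the class-center-subtracted residuals, and vice versa.

**Dimensionality.**  Two standard measures (`dimensionality()`): the number
of principal components needed to reach the variance threshold, and the
participation ratio `(Σλ)² / Σλ²`.

**Movies.**  `movie_factorization()` treats consecutive frame pairs as
two-level augmentations of a pseudo base scene: within-pair (local in time)
variance faces the across-pair structure exactly as a parameter faces the
others.  A movie with zero local variance has invariance 1 and an undefined
factorization (returned as `NA` with a typed warning, since the operation
returns both scores at once).

```{r metrics-example}
dat <- gen_augmentation_responses(augmentation_sim_config(
  n_base_scenes = 30, params = default_sim_params(alignment = 0.5), seed = 1))
geometry_scores(dat$responses, dat$design)
```

## The rotation lesion

Correlation between factorization and decodability is suggestive; the
package includes the causal control.  `rotation_lesion()` computes the
principal axes of the class centers (inter-class PCs) and of the
center-subtracted residuals (intra-class PCs), then applies to the centers
the change of basis `W = Σ v_i_intra (v_i_inter)ᵀ` that rotates each
inter-class axis onto the corresponding intra-class axis, leaving
within-class deviations untouched:

`x → g + W (x_c − g) + (x − x_c)`

with `x_c` the class center and `g` the unweighted mean of centers.  Because
`W` is an isometry on the inter-class span, everything about the data except
the *orientation* of class structure relative to nuisance structure is
conserved: within-class deviations bitwise, within-class covariance, the
inter-center spectrum, pairwise center distances, and invariance to
non-class factors.  Factorization and cross-validated decoding accuracy
drop.  The operator as printed in the field's formulation applies `W` to raw
class centers; we rotate about the mean of centers instead, which preserves
the grand mean and all the conservation laws above while changing no
variance statistic — the uncentered variant would translate the population
arbitrarily.

The paired rank convention: `W` pairs as many components as the inter-class
covariance has nonzero eigenvalues (at most classes − 1) and requires the
intra-class rank to be at least that; eigenvector signs are fixed so each
component's largest-magnitude coefficient is positive, making `W`
reproducible.

**Shuffle null.**  `shuffle_null()` permutes the grouping labels (class
labels in grouped mode; the scene/parameter/level assignment as a block in
augmentation mode) and reports the observed metric's percentile (strict
rank) in the permutation distribution.  On structure-free data the
percentile is uniform; on structured data it pins near 100.

## Decoding

`train_linear_decoder()` wraps a linear-kernel SVM (binary, max-margin) and
a ridge-penalized multinomial logistic regression (multiclass, exposing
probabilities).  `cv_decode()` adds stratified outer folds with inner-CV
penalty selection, reporting accuracy against the exact chance level.
`alignment_sweep()` reproduces the few-shot simulation: ten binary features
encoded along unit axes, two of which (the decoder targets) meet at a
configurable cosine.  In the noiseless collinear limit the two targets share
an axis and the Bayes rate for either is 0.75 (their sum is −2, 0 or +2; the
sum-zero half is undecidable) — a closed form the tests pin.  Note that
few-shot accuracy is bounded well below 1 even for an orthogonal, noiseless
code: with K = 2 examples per sign, the eight non-target features are
in-sample confounds of the same magnitude as the signal, and measured
accuracy is ≈ 0.73–0.75, rising toward 1 by K ≈ 10.  The simulation's noise
level (0.5) and test size (200) are package defaults, exposed in
`binary_factor_config()`.

## Predictivity scores

Three ways to score a representation against target data:

* `encoding_fit()` — cross-validated ridge regression from the
  representation's top principal components (default 300, capped at rank)
  onto each target unit; per-target score is the Pearson correlation of
  concatenated held-out predictions, aggregated by the median.  Both the PCA
  and the penalty selection are refit inside each training fold.  Fitting
  the components on all conditions at once would leak test information into
  the projection; the per-fold choice is deliberate even though zoo-scale
  analyses often fit components once per image set.
* `rdm_similarity()` — Spearman correlation (average ranks on ties) between
  the strict upper triangles of the two conditions × conditions dot-product
  similarity matrices.  The field often calls these "dissimilarity"
  matrices; the entries here are similarities, which leaves a rank
  correlation unchanged up to sign conventions applied to both inputs.
* `behavioral_signatures()` / `signature_correlation()` — converts
  classifier probabilities into the image-difficulty vector I1 and the
  image-by-distractor confusion matrix I2 with the two-alternative rule
  `i2 = p_d / (p_true + p_d)`, the minimal probability-consistent choice;
  `i1` is the mean of `1 − i2` over distractors.  Signatures from a model
  and from behavioral data are compared by Pearson correlation over defined
  cells.

No noise-ceiling normalization is applied anywhere: it rescales all models
identically and cannot change model rankings, and estimating it needs trial
repeats that are not generally available.

## Meta-analysis

`layer_average()` collapses a (model, layer) record table to one row per
model by averaging the final five representational layers — single-layer
metrics are hostage to the specific operation (convolution, pooling) that
precedes them.  `metric_fit_correlation()` reports the Spearman correlation
between a metric and a predictivity column across models, with a bootstrap
SD over models (models, not layers, are the exchangeable unit after
averaging).  `combined_metric_regression()` fits OLS of predictivity on a
metric set over 80% of models and reports the Spearman correlation between
predicted and observed predictivity on the held-out 20%, averaged over 100
splits.  Metric columns are used raw, not standardized: Spearman on
predictions is invariant to monotone rescaling, so standardization could
only change multi-metric weighting, not single-metric results.

## Synthetic data: what it emulates, and what it does not

Every generator plants geometry that the metrics must recover:

* `gen_augmentation_responses()` emulates an augmented image set — 100 base
  scenes × 4 parameters × 10 levels (4000 conditions) by default — at the
  *feature* level.  Each parameter owns an orthonormal latent subspace;
  pairwise subspace alignment is set through the first principal angle
  (cosine `sqrt(a_p a_q)`, one interpretable knob; remaining angles 90°);
  level offsets are Gaussian in the subspace; isotropic Gaussian noise is
  added.  Offsets are pre-scaled by `n_levels / (n_levels − 1)` so the
  package's n-denominator variance estimator is unbiased for the configured
  variance.  Base-scene identity occupies its own orthogonal subspace.
  `ground_truth_factorization()` evaluates the covariance-based score on the
  generating covariances, giving an exact recovery target.
* `gen_class_dataset()` plants class centers at a controlled principal angle
  to the within-class subspace — the grouped-mode testbed for the lesion.
* `gen_movie_responses()` produces paired frames with local/global
  subspaces at a controlled angle.
* `gen_binary_factor_data()` is the ten-binary-feature simulation above.
* `gen_model_table()` fabricates a model zoo with a planted linear
  metric → predictivity relationship for the meta-analysis.

What passing these tests shows: the estimators recover planted geometry,
respect their bounds, are invariant to orthogonal transforms, and behave
correctly under their nulls.  What it does not show: anything about real
neural data, whose noise is non-isotropic and non-Gaussian, whose "base
scenes" differ along the very parameters being varied (so scene-to-scene
variance bleeds into every other-parameter subspace), and whose sampling of
images is far from balanced.  Pixel-level rendering, real movies, spiking
and fMRI preprocessing, and actual network activations are all out of scope;
the augmentation ranges used to build such image sets (pose angles in
[−90°, 90°], crops of 20–100%, brightness/contrast/saturation jitters of
±0.4, hue ±0.1) are documented here as design metadata only.

## Numerical choices

* Variance uses the n denominator everywhere; PCA always mean-centers;
  projections are affine about the subspace centroid.
* Component counts take the *smallest* k whose cumulative explained-variance
  fraction reaches the threshold (ties toward smaller k); eigenvalues below
  `1e-12` of the maximum count as zero rank.
* Undefined scores (zero parameter variance, zero covariance norm, zero
  total variance, degenerate subspaces) raise typed conditions rather than
  returning sentinels, so a batch analysis cannot silently average 0/0
  artifacts.  The single exception is the movie score, which returns both
  quantities at once: an undefined factorization is `NA` with a typed
  warning while invariance (still well-defined, equal to 1) is returned.
* Within-subspace invariance needs a subspace for the *target* parameter's
  own structure.  In grouped mode that is the class centers.  In
  augmentation mode the analogous object is the set of within-scene
  deviations of the target parameter's level responses (per-scene means
  would remove exactly the variance of interest), and PCA runs on those
  deviations.
* Stochastic steps (fold assignment, permutations, bootstrap, generators)
  take explicit integer seeds, default 0, and are bitwise reproducible.
* Decoders: SVM cost and glmnet lambda are mapped onto one "regularization"
  scale (penalty; SVM cost is its reciprocal); the default selection grid is
  {0.01, 0.1, 1, 10, 100}; solver tolerances are tightened (1e-6 / 1e-10)
  for cross-platform determinism.
* Test and example problem sizes (e.g. 100-scene designs, 200-replicate
  null calibrations, 200-model zoos, 100-replicate sweeps) were chosen as
  the smallest sizes at which the statistical assertions have comfortable
  margins; all are package-level choices and scale up freely.

## Known limitations

* The other-parameter subspace uses only the per-scene averages (one vector
  per base scene), the literal reading of the averaging construction; an
  alternative would add the raw other-parameter augmentation responses as
  extra points.  With scene-to-scene variance present the two differ little,
  but the choice is visible at extreme thresholds.
* Subspace alignment is parameterized by the first principal angle only;
  codes whose overlap is spread across many small angles are generated only
  approximately by composing parameters of higher subspace dimension.
* The I2 rule is the probability-ratio two-alternative form; d′-based
  variants used by some behavioral benchmarks are not implemented.
* File I/O covers CSV/TSV (and YAML for configuration); binary containers
  are intentionally not part of the interface.
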