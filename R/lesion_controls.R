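#' Fit the class structure of a labeled population
#'
#' Computes class centers, inter-class principal components (PCA of the
#' centered class centers), intra-class principal components (PCA of the
#' responses with their class centers subtracted), and the change-of-basis
#' operator `W = sum_i v_i_intra (v_i_inter)^T` that rotates each inter-class
#' PC onto the corresponding intra-class PC.  `W` restricted to the span of
#' the inter-class PCs is an isometry.
#'
#' @param responses a [response_matrix()].
#' @param labels class label per condition (character/factor), or a
#'   grouped-mode [augmentation_design()].
#' @return an object of class `class_structure`: `class_labels`,
#'   `class_centers`, `global_center` (unweighted mean of class centers),
#'   `inter_pcs`, `intra_pcs` (features x M orthonormal), `rotation`
#'   (features x features), `n_paired` (M).
#' @export
fit_class_structure <- function(responses, labels) {
  responses <- as_response_matrix(responses)
  labels <- resolve_labels(responses, labels)
  counts <- table(labels)
  assert_that(length(counts) >= 2, "need at least 2 classes", "rank_error")
  if (any(counts < 2))
    fg_stop("every class needs at least 2 conditions (singleton class found)",
            "rank_error")
  X <- rm_values(responses)
  ctr <- class_centers(X, labels)
  gctr <- colMeans(ctr)
  inter <- pca_decomp(ctr)
  M <- length(inter$values)
  resid <- X - ctr[labels, , drop = FALSE]
  intra <- pca_decomp(resid)
  if (length(intra$values) < M)
    fg_stop(sprintf("intra-class rank %d < inter-class rank %d: cannot pair components",
                    length(intra$values), M), "rank_error")
  v_inter <- fix_signs(inter$basis[, seq_len(M), drop = FALSE])
  v_intra <- fix_signs(intra$basis[, seq_len(M), drop = FALSE])
  W <- v_intra %*% t(v_inter)
  structure(list(class_labels = labels, class_centers = ctr,
                 global_center = gctr, inter_pcs = v_inter,
                 intra_pcs = v_intra, rotation = W, n_paired = M),
            class = "class_structure")
}

#' Rotation lesion of class geometry
#'
#' Applies the basis rotation that maps inter-class principal axes onto
#' intra-class principal axes: each response becomes
#' `g + W (x_c - g) + (x - x_c)` where `x_c` is its class center and `g` the
#' unweighted mean of class centers.  Within-class deviations are preserved
#' bitwise; the between-class center geometry is rotated (isometrically) into
#' the intra-class subspace, selectively destroying factorization of class
#' from non-class variance while conserving within-class covariance, the
#' inter-center variance spectrum, pairwise center distances, and invariance
#' to non-class factors.
#'
#' @inheritParams fit_class_structure
#' @return a transformed [response_matrix()] with the same condition ids; the
#'   fitted `class_structure` is attached as attribute `"class_structure"`.
#' @export
rotation_lesion <- function(responses, labels) {
  responses <- as_response_matrix(responses)
  labels <- resolve_labels(responses, labels)
  cs <- fit_class_structure(responses, labels)
  X <- rm_values(responses)
  ctr <- cs$class_centers[labels, , drop = FALSE]
  centered_centers <- sweep(ctr, 2, cs$global_center)
  new_centers <- sweep(centered_centers %*% t(cs$rotation), 2,
                       cs$global_center, `+`)
  out <- response_matrix(new_centers + (X - ctr),
                         condition_ids = condition_ids(responses),
                         feature_ids = colnames(responses))
  attr(out, "class_structure") <- cs
  out
}

#' Permutation null distribution for a factorization metric
#'
#' Re-computes a factorization metric after permuting the grouping labels
#' uniformly at random: in grouped mode the class labels are shuffled (the
#' object-identity shuffle control); in augmentation mode the
#' (base scene, parameter, level) assignment of conditions is permuted as a
#' block, which preserves the design's structure while destroying its
#' relation to the responses.
#'
#' @inheritParams param_variance
#' @param metric `"factorization_pca"` or `"factorization_cov"`.
#' @param n_permutations number of label permutations (a warning is logged
#'   below 20: the percentile becomes unstable).
#' @param seed integer RNG seed.
#' @param threshold PCA threshold (used by the pca variant).
#' @return an object of class `null_distribution`: `observed`,
#'   `null_samples`, `percentile` (fraction of null samples strictly below
#'   the observed value, times 100), `n_permutations`, `seed`, `metric`.
#' @export
shuffle_null <- function(responses, design, param,
                         metric = c("factorization_pca", "factorization_cov"),
                         n_permutations = 99L, seed = 0L, threshold = 0.9) {
  metric <- match.arg(metric)
  responses <- as_response_matrix(responses)
  design <- align_design(responses, design)
  if (n_permutations < 20)
    fg_warn("fewer than 20 permutations: percentile estimate is unstable",
            "unstable_percentile")
  eval_metric <- function(d) {
    if (metric == "factorization_pca")
      factorization_pca(responses, d, param, threshold)
    else factorization_cov(responses, d, param)
  }
  observed <- eval_metric(design)
  grouping_cols <- if (design_mode(design) == "grouped") "class_label"
  else c("base_scene_id", "varied_param", "level")
  nulls <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      perm <- sample.int(nrow(design))
      d <- design
      d[, grouping_cols] <- design[perm, grouping_cols]
      eval_metric(d)
    }, 0)
  })
  structure(list(observed = observed, null_samples = nulls,
                 percentile = 100 * mean(nulls < observed),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), metric = metric),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution: %s observed %.4f, percentile %.1f over %d permutations>\n",
              x$metric, x$observed, x$percentile, x$n_permutations))
  invisible(x)
}

resolve_labels <- function(responses, labels) {
  if (inherits(labels, "augmentation_design")) {
    assert_that(design_mode(labels) == "grouped",
                "class structure needs a grouped-mode design", "design_error")
    labels <- align_design(responses, labels)$class_label
  }
  labels <- as.character(labels)
  assert_that(length(labels) == n_conditions(responses),
              "one label per condition required", "domain_error")
  labels
}
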