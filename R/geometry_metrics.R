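#' Parameter-induced variance
#'
#' The variance a scene parameter injects into the population response.  In
#' augmentation mode this is, for each base scene, the total variance (summed
#' over features, n-denominator) of the responses to that scene's levels of
#' the parameter, averaged across base scenes.  In grouped mode the
#' pseudo-parameter `"class"` gives the variance of class centers about their
#' mean and `"non_class"` the mean within-class total variance.
#'
#' @param responses a [response_matrix()].
#' @param design a matching [augmentation_design()].
#' @param param a scene parameter present in the design, or `"class"` /
#'   `"non_class"` in grouped mode.
#' @return a single non-negative number.
#' @export
param_variance <- function(responses, design, param) {
  responses <- as_response_matrix(responses)
  design <- align_design(responses, design)
  check_param(design, param)
  X <- rm_values(responses)
  if (design_mode(design) == "augmentation") {
    rows <- which(design$varied_param == param)
    groups <- split(rows, design$base_scene_id[rows])
    mean(vapply(groups, function(ix) total_variance(X[ix, , drop = FALSE]), 0))
  } else if (param == "class") {
    total_variance(class_centers(X, design$class_label))
  } else {
    groups <- split(seq_len(nrow(X)), design$class_label)
    mean(vapply(groups, function(ix) total_variance(X[ix, , drop = FALSE]), 0))
  }
}

#' Total variance across all conditions of a design
#'
#' The variance induced by all parameters together: total variance (summed
#' over features) of every condition about the global mean.
#' @inheritParams param_variance
#' @export
all_param_variance <- function(responses, design) {
  responses <- as_response_matrix(responses)
  design <- align_design(responses, design)
  total_variance(rm_values(responses))
}

#' Other-parameter subspace
#'
#' The principal subspace capturing the bulk of the variance driven by every
#' parameter *except* the one of interest.  Augmentation mode: responses for
#' each base scene are averaged over the parameter's levels (washing out that
#' parameter's variance), and PCA is run on the resulting one-vector-per-scene
#' set; the subspace is the smallest leading set of components reaching the
#' cumulative explained-variance threshold.  Grouped mode: for `"class"` the
#' subspace comes from the class-center-subtracted residuals; for
#' `"non_class"` from the class centers.
#'
#' @inheritParams param_variance
#' @param threshold cumulative explained-variance fraction in (0, 1]
#'   (default 0.9).
#' @return an object of class `subspace`: orthonormal `basis`
#'   (features x k), `center`, eigenvalues and the threshold used.
#' @export
other_param_subspace <- function(responses, design, param, threshold = 0.9) {
  responses <- as_response_matrix(responses)
  design <- align_design(responses, design)
  check_param(design, param)
  X <- rm_values(responses)
  if (design_mode(design) == "augmentation") {
    rows <- which(design$varied_param == param)
    groups <- split(rows, design$base_scene_id[rows])
    assert_that(length(groups) >= 2,
                "other-parameter subspace needs at least 2 base scenes",
                "degenerate_subspace")
    pts <- t(vapply(groups, function(ix) colMeans(X[ix, , drop = FALSE]),
                    numeric(ncol(X))))
  } else if (param == "class") {
    ctr <- class_centers(X, design$class_label)
    pts <- X - ctr[design$class_label, , drop = FALSE] +
      matrix(colMeans(X), nrow(X), ncol(X), byrow = TRUE)
  } else {
    pts <- class_centers(X, design$class_label)
  }
  dec <- pca_decomp(pts)
  if (length(dec$values) == 0)
    fg_stop("all averaged responses identical: other-parameter subspace is rank 0",
            "degenerate_subspace")
  k <- pick_k(dec$values, threshold)
  new_subspace(dec$basis[, seq_len(k), drop = FALSE], dec$center, threshold,
               dec$values[seq_len(k)])
}

new_subspace <- function(basis, center, threshold, values = NULL) {
  structure(list(basis = basis, center = center,
                 variance_threshold = threshold, values = values),
            class = "subspace")
}

#' @export
print.subspace <- function(x, ...) {
  cat(sprintf("<subspace: %d components in %d-d feature space (threshold %.2f)>\n",
              ncol(x$basis), nrow(x$basis), x$variance_threshold))
  invisible(x)
}

#' PCA-based factorization of a scene parameter
#'
#' The fraction of parameter-induced variance that avoids the subspace
#' occupied by other parameters' variance:
#' `1 - var_param_in_other_subspace / var_param`, where the numerator repeats
#' the [param_variance()] computation on responses projected (affinely, about
#' the subspace center) onto the [other_param_subspace()].
#'
#' @inheritParams other_param_subspace
#' @return a number in \[0, 1\]; 1 means fully factorized (no overlap).
#' @export
factorization_pca <- function(responses, design, param, threshold = 0.9) {
  responses <- as_response_matrix(responses)
  design <- align_design(responses, design)
  v <- param_variance(responses, design, param)
  if (v <= 0)
    fg_stop(sprintf("parameter '%s' induces zero variance: factorization undefined", param),
            "undefined_score")
  ss <- other_param_subspace(responses, design, param, threshold)
  proj <- project_affine(rm_values(responses), ss$basis, ss$center)
  projected <- response_matrix(proj, condition_ids = condition_ids(responses))
  v_in <- param_variance(projected, design, param)
  clamp01(1 - v_in / v)
}

#' Covariance-based factorization of a scene parameter
#'
#' One minus the normalized Frobenius inner product of the covariance
#' matrices induced by the parameter of interest and by all other parameters:
#' `1 - <C_param, C_other>_F / (||C_param||_F ||C_other||_F)`.  Parameter-free
#' (no PCA threshold).  In augmentation mode `C_param` is the covariance of a
#' base scene's responses across the parameter's levels, averaged over
#' scenes, and `C_other` pools the same construction over all other
#' parameters; in grouped mode the class-center covariance faces the mean
#' within-class covariance.
#'
#' @inheritParams param_variance
#' @return a number in \[0, 1\].
#' @seealso [factorization_from_cov_pair()] for scoring externally built
#'   covariance pairs.
#' @export
factorization_cov <- function(responses, design, param) {
  responses <- as_response_matrix(responses)
  design <- align_design(responses, design)
  check_param(design, param)
  X <- rm_values(responses)
  if (design_mode(design) == "augmentation") {
    params <- design_params(design)
    assert_that(length(params) >= 2,
                "covariance factorization needs at least 2 parameters",
                "design_error")
    cov_param <- mean_group_cov(X, design, param)
    others <- setdiff(params, param)
    cov_other <- Reduce(`+`, lapply(others, function(q) mean_group_cov(X, design, q))) /
      length(others)
  } else {
    ctr <- class_centers(X, design$class_label)
    groups <- split(seq_len(nrow(X)), design$class_label)
    within <- Reduce(`+`, lapply(groups, function(ix) cov_n(X[ix, , drop = FALSE]))) /
      length(groups)
    if (param == "class") {
      cov_param <- cov_n(ctr); cov_other <- within
    } else {
      cov_param <- within; cov_other <- cov_n(ctr)
    }
  }
  factorization_from_cov_pair(cov_param, cov_other)
}

mean_group_cov <- function(X, design, param) {
  rows <- which(design$varied_param == param)
  groups <- split(rows, design$base_scene_id[rows])
  Reduce(`+`, lapply(groups, function(ix) cov_n(X[ix, , drop = FALSE]))) /
    length(groups)
}

#' Covariance-pair factorization score
#'
#' Score two induced covariance matrices directly:
#' `1 - <A, B>_F / (||A||_F ||B||_F)`.  Bounded in \[0, 1\] for positive
#' semi-definite inputs (Cauchy-Schwarz and non-negativity of the inner
#' product of PSD matrices).
#'
#' @param cov_param,cov_other symmetric PSD matrices of equal dimension.
#' @return a number in \[0, 1\].
#' @export
factorization_from_cov_pair <- function(cov_param, cov_other) {
  cov_param <- as.matrix(cov_param); cov_other <- as.matrix(cov_other)
  assert_that(all(dim(cov_param) == dim(cov_other)) &&
                nrow(cov_param) == ncol(cov_param),
              "covariances must be square and of equal dimension", "domain_error")
  assert_that(max(abs(cov_param - t(cov_param))) <= 1e-10 * max(1, max(abs(cov_param))) &&
                max(abs(cov_other - t(cov_other))) <= 1e-10 * max(1, max(abs(cov_other))),
              "covariances must be symmetric", "domain_error")
  na <- sqrt(sum(cov_param^2)); nb <- sqrt(sum(cov_other^2))
  if (na == 0 || nb == 0)
    fg_stop("a covariance is identically zero: factorization undefined",
            "undefined_score")
  clamp01(1 - sum(cov_param * cov_other) / (na * nb))
}

#' Invariance (tolerance) to a scene parameter
#'
#' `1 - var_param / var_all`: the closer to 1, the less the parameter moves
#' the population response relative to the total variance across all
#' conditions of the design.
#'
#' @inheritParams param_variance
#' @return a number `<= 1` (1 = perfectly invariant).
#' @export
invariance <- function(responses, design, param) {
  v_all <- all_param_variance(responses, design)
  if (v_all <= 0)
    fg_stop("total variance is zero: invariance undefined", "undefined_score")
  1 - param_variance(responses, design, param) / v_all
}

#' Invariance measured inside another parameter's subspace
#'
#' Projects all responses into the principal subspace of the structure driven
#' by `target_param` (grouped mode: class centers; augmentation mode: the
#' within-scene deviations of the target parameter's level responses) and
#' recomputes [invariance()] to `param` inside it.  High values indicate a
#' readout subspace for `target_param` that is tolerant to `param`.
#'
#' @inheritParams other_param_subspace
#' @param target_param the parameter whose subspace defines the readout.
#' @return a number `<= 1`.
#' @export
invariance_within_subspace <- function(responses, design, param, target_param,
                                       threshold = 0.9) {
  responses <- as_response_matrix(responses)
  design <- align_design(responses, design)
  check_param(design, param)
  check_param(design, target_param)
  X <- rm_values(responses)
  if (design_mode(design) == "grouped") {
    pts <- if (target_param == "class") class_centers(X, design$class_label)
    else X - class_centers(X, design$class_label)[design$class_label, , drop = FALSE]
  } else {
    rows <- which(design$varied_param == target_param)
    groups <- split(rows, design$base_scene_id[rows])
    pts <- do.call(rbind, lapply(groups, function(ix) {
      sub <- X[ix, , drop = FALSE]
      sweep(sub, 2, colMeans(sub))
    }))
  }
  dec <- pca_decomp(pts)
  if (length(dec$values) == 0)
    fg_stop("target-parameter structure is degenerate: subspace undefined",
            "degenerate_subspace")
  k <- pick_k(dec$values, threshold)
  basis <- dec$basis[, seq_len(k), drop = FALSE]
  proj <- project_affine(X, basis, colMeans(X))
  projected <- response_matrix(proj, condition_ids = condition_ids(responses))
  invariance(projected, design, param)
}

#' Effective dimensionality of a response matrix
#'
#' Two standard measures over the eigenvalues of the (mean-centered,
#' n-denominator) feature-space covariance: the number of leading components
#' needed to reach a cumulative explained-variance threshold, and the
#' participation ratio `(sum(lambda))^2 / sum(lambda^2)`.
#'
#' @param responses a [response_matrix()].
#' @param method `"pc_count"` or `"participation_ratio"`.
#' @param threshold cumulative variance fraction for `"pc_count"`.
#' @return a number `>= 1`.
#' @export
dimensionality <- function(responses, method = c("pc_count", "participation_ratio"),
                           threshold = 0.9) {
  method <- match.arg(method)
  responses <- as_response_matrix(responses)
  dec <- pca_decomp(rm_values(responses))
  if (length(dec$values) == 0)
    fg_stop("zero total variance: dimensionality undefined", "undefined_score")
  if (method == "pc_count") as.numeric(pick_k(dec$values, threshold))
  else sum(dec$values)^2 / sum(dec$values^2)
}

#' Factorization and invariance for natural-movie responses
#'
#' For time-ordered frame responses, each consecutive frame pair is treated
#' as a two-level "augmentation" of a pseudo base scene (the pair).  Local
#' (frame-to-frame) variance plays the role of parameter-induced variance;
#' the other-parameter subspace comes from the pair means (variance that is
#' non-local in time); scores are computed exactly as in augmentation mode.
#'
#' @param frames a time-ordered [response_matrix()] with an even number of
#'   rows (>= 4).
#' @param variant `"pca"` or `"cov"` factorization.
#' @param threshold cumulative variance fraction for the `"pca"` variant.
#' @return a list with elements `factorization` and `invariance`.  If the
#'   movie has zero local variance the factorization is undefined: `NA` is
#'   returned for it with a warning, and invariance is 1.
#' @export
movie_factorization <- function(frames, variant = c("pca", "cov"), threshold = 0.9) {
  variant <- match.arg(variant)
  frames <- as_response_matrix(frames)
  X <- rm_values(frames)
  n <- nrow(X)
  assert_that(n >= 4 && n %% 2 == 0,
              "movie needs an even number of frames, at least 4", "domain_error")
  pair_of <- rep(seq_len(n / 2), each = 2)
  pairs <- split(seq_len(n), pair_of)
  var_local <- mean(vapply(pairs, function(ix) total_variance(X[ix, , drop = FALSE]), 0))
  var_all <- total_variance(X)
  if (var_all <= 0)
    fg_stop("zero total variance across frames", "undefined_score")
  inv <- 1 - var_local / var_all
  if (var_local <= 0) {
    fg_warn("zero local (within-pair) variance: movie factorization undefined",
            "undefined_score")
    return(list(factorization = NA_real_, invariance = 1, variant = variant))
  }
  pair_means <- t(vapply(pairs, function(ix) colMeans(X[ix, , drop = FALSE]),
                         numeric(ncol(X))))
  if (variant == "pca") {
    dec <- pca_decomp(pair_means)
    if (length(dec$values) == 0)
      fg_stop("pair means are all identical: other-subspace is rank 0",
              "degenerate_subspace")
    k <- pick_k(dec$values, threshold)
    basis <- dec$basis[, seq_len(k), drop = FALSE]
    proj <- project_affine(X, basis, dec$center)
    v_in <- mean(vapply(pairs, function(ix) total_variance(proj[ix, , drop = FALSE]), 0))
    fact <- clamp01(1 - v_in / var_local)
  } else {
    cov_local <- Reduce(`+`, lapply(pairs, function(ix) cov_n(X[ix, , drop = FALSE]))) /
      length(pairs)
    cov_global <- cov_n(pair_means)
    fact <- factorization_from_cov_pair(cov_local, cov_global)
  }
  list(factorization = fact, invariance = inv, variant = variant)
}

#' All geometry scores for a response matrix and design
#'
#' Convenience wrapper computing, per parameter, both factorization variants
#' and invariance, plus the two dimensionality measures of the full response
#' set.
#'
#' @inheritParams other_param_subspace
#' @return a list of class `geometry_scores` with a per-parameter data frame
#'   (`scores`) and `dimensionality` (pc_count, participation_ratio).
#' @export
geometry_scores <- function(responses, design, threshold = 0.9) {
  responses <- as_response_matrix(responses)
  design <- align_design(responses, design)
  params <- design_params(design)
  rows <- lapply(params, function(p) {
    data.frame(
      param = p,
      factorization_pca = factorization_pca(responses, design, p, threshold),
      factorization_cov = factorization_cov(responses, design, p),
      invariance = invariance(responses, design, p),
      stringsAsFactors = FALSE
    )
  })
  structure(list(
    scores = do.call(rbind, rows),
    dimensionality = c(
      pc_count = dimensionality(responses, "pc_count", threshold),
      participation_ratio = dimensionality(responses, "participation_ratio")
    ),
    threshold = threshold
  ), class = "geometry_scores")
}

#' @export
print.geometry_scores <- function(x, ...) {
  cat("Population geometry scores (threshold", x$threshold, ")\n")
  print(x$scores, row.names = FALSE, digits = 4)
  cat(sprintf("dimensionality: pc_count = %d, participation ratio = %.2f\n",
              as.integer(x$dimensionality["pc_count"]),
              x$dimensionality["participation_ratio"]))
  invisible(x)
}

check_param <- function(design, param) {
  ps <- design_params(design)
  if (!param %in% ps)
    fg_stop(sprintf("parameter '%s' not present in design (have: %s)",
                    param, paste(ps, collapse = ", ")), "key_error")
}

class_centers <- function(X, labels) {
  groups <- split(seq_len(nrow(X)), labels)
  ctr <- t(vapply(groups, function(ix) colMeans(X[ix, , drop = FALSE]),
                  numeric(ncol(X))))
  rownames(ctr) <- names(groups)
  ctr
}

clamp01 <- function(x) min(max(x, 0), 1)
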