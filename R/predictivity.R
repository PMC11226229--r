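#' Cross-validated ridge encoding fit
#'
#' Scores how well a feature representation linearly predicts target
#' responses (units or voxels).  Per outer fold, features are mean-centered
#' and projected onto the top principal components fit on the training
#' conditions only (at most `encoding_n_components`, default 300); a
#' multi-target ridge regression is fit with the penalty selected by inner
#' cross-validation on the training fold; held-out predictions are
#' accumulated.  The per-target score is the Pearson correlation between the
#' concatenated held-out predictions and the actual values; the aggregate is
#' the median over targets.
#'
#' @param features a [response_matrix()] of model features.
#' @param targets a [response_matrix()] of measured responses with the same
#'   condition ids in the same order.
#' @param config an [analysis_config()].
#' @return an object of class `encoding_fit_result`: `per_target_score`
#'   (named, `NA` for constant targets, which are excluded from the
#'   aggregate), `aggregate` (median), `chosen_penalty` per fold,
#'   `n_components` per fold.
#' @export
encoding_fit <- function(features, targets, config = analysis_config()) {
  features <- as_response_matrix(features)
  targets <- as_response_matrix(targets)
  assert_that(identical(condition_ids(features), condition_ids(targets)),
              "features and targets must share condition ids in the same order",
              "alignment_error")
  X <- rm_values(features); Y <- rm_values(targets)
  n <- nrow(X)
  assert_that(n > config$cv_folds, "need more conditions than folds",
              "domain_error")
  folds <- config$cv_folds
  fold_id <- withr::with_seed(config$seed,
                              sample(rep_len(seq_len(folds), n)))
  pred <- matrix(NA_real_, n, ncol(Y))
  chosen <- numeric(folds)
  ncomp <- integer(folds)
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f); te <- which(fold_id == f)
    ctr <- colMeans(X[tr, , drop = FALSE])
    Xtr <- sweep(X[tr, , drop = FALSE], 2, ctr)
    sv <- svd(Xtr)
    rank <- sum(sv$d > 1e-10 * max(sv$d))
    k <- min(config$encoding_n_components, rank)
    V <- sv$v[, seq_len(k), drop = FALSE]
    Ztr <- Xtr %*% V
    Zte <- sweep(X[te, , drop = FALSE], 2, ctr) %*% V
    # inner CV over the penalty grid (training conditions only)
    inner <- withr::with_seed(config$seed + f,
                              sample(rep_len(seq_len(min(folds, length(tr) - 1)),
                                             length(tr))))
    grid <- config$ridge_penalty_grid
    mse <- vapply(grid, function(lam) {
      mean(vapply(seq_len(max(inner)), function(g) {
        itr <- inner != g; ite <- inner == g
        yp <- ridge_predict(Ztr[itr, , drop = FALSE], Y[tr[itr], , drop = FALSE],
                            Ztr[ite, , drop = FALSE], lam)
        mean((yp - Y[tr[ite], , drop = FALSE])^2)
      }, 0))
    }, 0)
    lam <- grid[which.min(mse)]
    chosen[f] <- lam; ncomp[f] <- k
    pred[te, ] <- ridge_predict(Ztr, Y[tr, , drop = FALSE], Zte, lam)
  }
  scores <- vapply(seq_len(ncol(Y)), function(j) {
    if (stats::sd(Y[, j]) == 0) return(NA_real_)
    stats::cor(pred[, j], Y[, j])
  }, 0)
  names(scores) <- colnames(Y)
  structure(list(per_target_score = scores,
                 aggregate = stats::median(scores, na.rm = TRUE),
                 chosen_penalty = chosen, n_components = ncomp,
                 seed = config$seed),
            class = "encoding_fit_result")
}

# closed-form multi-target ridge: one SVD serves every target column
ridge_predict <- function(Ztr, Ytr, Zte, lambda) {
  ybar <- colMeans(Ytr)
  Yc <- sweep(Ytr, 2, ybar)
  sv <- svd(Ztr)
  shrink <- sv$d / (sv$d^2 + lambda)
  beta <- sv$v %*% (shrink * (t(sv$u) %*% Yc))
  sweep(Zte %*% beta, 2, ybar, `+`)
}

#' @export
print.encoding_fit_result <- function(x, ...) {
  cat(sprintf("<encoding_fit_result: median held-out r = %.3f over %d targets>\n",
              x$aggregate, length(x$per_target_score)))
  invisible(x)
}

#' Representational similarity between two representations
#'
#' Builds the conditions x conditions matrix of pairwise dot products for
#' each representation and returns the Spearman rank correlation over the
#' strictly-upper-triangle entries (diagonal excluded).  Ties receive average
#' ranks.
#'
#' @param features_a,features_b [response_matrix()]s over the same conditions
#'   in the same order (feature counts may differ).
#' @return a number in \[-1, 1\].
#' @export
rdm_similarity <- function(features_a, features_b) {
  features_a <- as_response_matrix(features_a)
  features_b <- as_response_matrix(features_b)
  assert_that(identical(condition_ids(features_a), condition_ids(features_b)),
              "representations must share condition ids in the same order",
              "alignment_error")
  n <- n_conditions(features_a)
  if (n < 3) fg_stop("need at least 3 conditions (3 pairs) for a rank correlation",
                     "too_few_pairs")
  sa <- tcrossprod(rm_values(features_a))
  sb <- tcrossprod(rm_values(features_b))
  ut <- upper.tri(sa)
  stats::cor(sa[ut], sb[ut], method = "spearman")
}

#' Pairwise similarity matrix of a representation
#'
#' @param features a [response_matrix()].
#' @return symmetric conditions x conditions matrix of dot products, with
#'   condition ids as dimnames.
#' @export
similarity_matrix <- function(features) {
  features <- as_response_matrix(features)
  s <- tcrossprod(rm_values(features))
  dimnames(s) <- list(condition_ids(features), condition_ids(features))
  s
}

#' Behavioral signatures from classifier probabilities
#'
#' Converts per-image class probabilities into the two standard behavioral
#' signatures: the image-by-distractor confusion matrix I2, with
#' `i2[i, d] = p_d / (p_true + p_d)` (the two-alternative error rate when
#' image i's true class faces distractor d), and the per-image difficulty
#' vector I1, `i1[i] = mean over d != true of (1 - i2[i, d])`.
#'
#' @param class_probabilities conditions x classes matrix; rows non-negative
#'   and summing to 1 (tolerance 1e-6); column names are the class
#'   vocabulary.
#' @param true_labels true class per row.
#' @return an object of class `behavioral_signature`: `i1`, `i2` (NA at the
#'   true-class column and at undefined cells where `p_true + p_d = 0`),
#'   `classes`, `true_labels`.
#' @export
behavioral_signatures <- function(class_probabilities, true_labels) {
  P <- as.matrix(class_probabilities)
  assert_that(!is.null(colnames(P)), "class probabilities need column names",
              "domain_error")
  assert_that(all(P >= -1e-12), "probabilities must be non-negative", "domain_error")
  assert_that(max(abs(rowSums(P) - 1)) <= 1e-6,
              "probability rows must sum to 1", "domain_error")
  true_labels <- as.character(true_labels)
  assert_that(all(true_labels %in% colnames(P)),
              "every true label must appear in the class vocabulary", "domain_error")
  classes <- colnames(P)
  n <- nrow(P)
  i2 <- matrix(NA_real_, n, length(classes), dimnames = list(rownames(P), classes))
  for (i in seq_len(n)) {
    pt <- P[i, true_labels[i]]
    for (d in classes) {
      if (d == true_labels[i]) next
      denom <- pt + P[i, d]
      i2[i, d] <- if (denom > 0) P[i, d] / denom else NA_real_
    }
  }
  i1 <- rowMeans(1 - i2, na.rm = TRUE)
  structure(list(i1 = i1, i2 = i2, classes = classes, true_labels = true_labels),
            class = "behavioral_signature")
}

#' Correlate two behavioral signatures
#'
#' Pearson correlation over the I1 entries and over the I2 cells defined in
#' both signatures (missing cells pairwise-deleted).
#'
#' @param model_sig,data_sig [behavioral_signatures()] objects over matching
#'   image sets and class vocabularies.
#' @return named numeric vector `c(i1_corr =, i2_corr =)`.
#' @export
signature_correlation <- function(model_sig, data_sig) {
  stopifnot(inherits(model_sig, "behavioral_signature"),
            inherits(data_sig, "behavioral_signature"))
  assert_that(identical(model_sig$classes, data_sig$classes) &&
                length(model_sig$i1) == length(data_sig$i1),
              "signatures must share image set and class vocabulary",
              "alignment_error")
  if (stats::sd(model_sig$i1) == 0 || stats::sd(data_sig$i1) == 0)
    fg_stop("zero-variance signature: correlation undefined", "undefined_score")
  i1_corr <- stats::cor(model_sig$i1, data_sig$i1)
  ok <- !is.na(model_sig$i2) & !is.na(data_sig$i2)
  a <- model_sig$i2[ok]; b <- data_sig$i2[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    fg_stop("zero-variance signature: correlation undefined", "undefined_score")
  c(i1_corr = i1_corr, i2_corr = stats::cor(a, b))
}
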