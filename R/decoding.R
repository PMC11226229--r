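#' Train a regularized linear decoder
#'
#' Two families: `"max_margin"` — a linear support-vector machine (binary
#' targets only), and `"multinomial_logistic"` — ridge-penalized multinomial
#' logistic regression exposing class probabilities.  `regularization` is on
#' the penalty scale (larger = stronger shrinkage); for the SVM the cost
#' parameter is its reciprocal.
#'
#' @param x numeric matrix of training points (rows) x features.
#' @param y labels, one per row (at least two classes; exactly two for
#'   `"max_margin"`).
#' @param kind `"max_margin"` or `"multinomial_logistic"`.
#' @param regularization positive penalty.
#' @return an object of class `linear_decoder` with `kind`, `classes`,
#'   `weights` (classes/1 x features), `offsets`, and a [predict] method
#'   returning labels, decision values or probabilities.
#' @export
train_linear_decoder <- function(x, y,
                                 kind = c("max_margin", "multinomial_logistic"),
                                 regularization = 1) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2)
    fg_stop("training labels contain a single class", "degenerate_label")
  assert_that(regularization > 0, "regularization must be positive", "domain_error")
  if (kind == "max_margin") {
    assert_that(length(classes) == 2, "max_margin decoder is binary only",
                "domain_error")
    fit <- e1071::svm(x, factor(y, levels = classes), kernel = "linear",
                      cost = 1 / regularization, scale = FALSE,
                      tolerance = 1e-6)
    w <- crossprod(fit$coefs, fit$SV)
    b <- -fit$rho
    model <- fit
  } else {
    fit <- glmnet::glmnet(x, factor(y, levels = classes),
                          family = "multinomial", alpha = 0,
                          lambda = regularization, standardize = FALSE,
                          thresh = 1e-10)
    cf <- stats::coef(fit)
    w <- t(vapply(cf, function(m) as.numeric(m)[-1], numeric(ncol(x))))
    b <- vapply(cf, function(m) as.numeric(m)[1], 0)
    model <- fit
  }
  structure(list(kind = kind, classes = classes, weights = w, offsets = b,
                 regularization = regularization, model = model),
            class = "linear_decoder")
}

#' @export
predict.linear_decoder <- function(object, newdata,
                                   type = c("class", "decision", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (object$kind == "max_margin") {
    if (type == "prob")
      fg_stop("max_margin decoder exposes decision values, not probabilities",
              "domain_error")
    pr <- predict(object$model, newdata, decision.values = TRUE)
    if (type == "decision") return(drop(attr(pr, "decision.values")))
    return(as.character(pr))
  }
  pr <- predict(object$model, newx = newdata, type = "response")[, , 1]
  pr <- matrix(pr, nrow = nrow(newdata),
               dimnames = list(NULL, object$classes))
  if (type == "prob") return(pr)
  scores <- predict(object$model, newx = newdata, type = "link")[, , 1]
  scores <- matrix(scores, nrow = nrow(newdata))
  if (type == "decision") return(scores)
  object$classes[max.col(pr, ties.method = "first")]
}

#' Cross-validated decoding accuracy
#'
#' Stratified k-fold classification accuracy.  When the regularization grid
#' has more than one value, the penalty is selected per outer fold by an
#' inner stratified cross-validation on the training folds only.
#'
#' @param responses a [response_matrix()] or plain matrix.
#' @param labels class label per condition.
#' @param folds number of outer folds (every class must reach every fold).
#' @param kind decoder family, see [train_linear_decoder()].
#' @param regularization_grid candidate penalties.
#' @param seed integer RNG seed (fold assignment).
#' @return an object of class `decoding_report`: `accuracy`,
#'   `per_class_accuracy`, `chance_level` (= 1 / number of classes),
#'   `n_train`, `n_test`, `regularization` chosen per fold, `seed`.
#' @export
cv_decode <- function(responses, labels, folds = 5L,
                      kind = c("multinomial_logistic", "max_margin"),
                      regularization_grid = c(0.01, 0.1, 1, 10, 100),
                      seed = 0L) {
  kind <- match.arg(kind)
  x <- if (inherits(responses, "response_matrix")) rm_values(responses)
  else as.matrix(responses)
  y <- as.character(labels)
  assert_that(length(y) == nrow(x), "one label per condition required",
              "domain_error")
  classes <- sort(unique(y))
  counts <- table(y)
  if (any(counts < folds))
    fg_stop(sprintf("smallest class has %d conditions < %d folds: cannot stratify",
                    min(counts), folds), "stratification_error")
  fold_id <- withr::with_seed(seed, stratified_folds(y, folds))
  pred <- character(length(y))
  chosen <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f); te <- which(fold_id == f)
    reg <- if (length(regularization_grid) == 1) regularization_grid else {
      inner_folds <- min(3L, min(table(y[tr])))
      inner_id <- withr::with_seed(seed + f, stratified_folds(y[tr], inner_folds))
      acc <- vapply(regularization_grid, function(r) {
        mean(vapply(seq_len(inner_folds), function(g) {
          itr <- tr[inner_id != g]; ite <- tr[inner_id == g]
          dec <- train_linear_decoder(x[itr, , drop = FALSE], y[itr], kind, r)
          mean(predict(dec, x[ite, , drop = FALSE]) == y[ite])
        }, 0))
      }, 0)
      regularization_grid[which.max(acc)]
    }
    chosen[f] <- reg
    dec <- train_linear_decoder(x[tr, , drop = FALSE], y[tr], kind, reg)
    pred[te] <- predict(dec, x[te, , drop = FALSE])
  }
  per_class <- vapply(classes, function(cl) mean(pred[y == cl] == cl), 0)
  structure(list(accuracy = mean(pred == y),
                 per_class_accuracy = stats::setNames(per_class, classes),
                 chance_level = 1 / length(classes),
                 n_train = length(y) - min(table(fold_id)),
                 n_test = length(y),
                 regularization = chosen, kind = kind,
                 seed = as.integer(seed)),
            class = "decoding_report")
}

#' @export
print.decoding_report <- function(x, ...) {
  cat(sprintf("<decoding_report: accuracy %.3f (chance %.3f, %d classes, %s)>\n",
              x$accuracy, x$chance_level, length(x$per_class_accuracy), x$kind))
  invisible(x)
}

# deterministic stratified fold assignment: within each class, shuffle then
# deal out folds round-robin
stratified_folds <- function(y, folds) {
  fold_id <- integer(length(y))
  for (cl in unique(y)) {
    ix <- which(y == cl)
    ix <- ix[sample.int(length(ix))]
    fold_id[ix] <- rep_len(seq_len(folds), length(ix))
  }
  fold_id
}

#' Few-shot decoding accuracy across axis alignments
#'
#' Replicates the factorization-vs-decoding simulation: for each combination
#' of target-axis alignment and training-set size K, fresh data are generated
#' with [gen_binary_factor_data()], a max-margin decoder is trained on the
#' K positive + K negative examples of each target variable, and held-out
#' accuracy (averaged over the two variables) is recorded.
#'
#' @param base_config a [binary_factor_config()] supplying all settings not
#'   swept over.
#' @param alignments alignment values to sweep.
#' @param k_values training examples per sign (K) to sweep.
#' @param n_replicates fresh datasets per cell.
#' @param seed integer RNG seed.
#' @param regularization SVM penalty (default 1).
#' @return a data.frame with columns `alignment`, `k`, `replicate`,
#'   `accuracy`.
#' @export
alignment_sweep <- function(base_config, alignments = c(0, 0.25, 0.5, 0.75, 1),
                            k_values = c(2L, 50L), n_replicates = 100L,
                            seed = 0L, regularization = 1) {
  stopifnot(inherits(base_config, "binary_factor_config"))
  grid <- expand.grid(alignment = alignments, k = k_values,
                      replicate = seq_len(n_replicates))
  acc <- withr::with_seed(seed, {
    cell_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
    vapply(seq_len(nrow(grid)), function(i) {
      cfg <- binary_factor_config(
        n_dims = base_config$n_dims, alignment = grid$alignment[i],
        noise_sd = base_config$noise_sd, k_train = grid$k[i],
        n_test = base_config$n_test, seed = cell_seeds[i])
      dat <- gen_binary_factor_data(cfg)
      mean(vapply(1:2, function(j) {
        dec <- train_linear_decoder(dat$train[[j]]$x, dat$train[[j]]$y,
                                    "max_margin", regularization)
        truth <- if (j == 1) dat$test$y1 else dat$test$y2
        mean(predict(dec, dat$test$x) == as.character(truth))
      }, 0))
    }, 0)
  })
  grid$accuracy <- acc
  grid[, c("alignment", "k", "replicate", "accuracy")]
}
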