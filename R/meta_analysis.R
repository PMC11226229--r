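#' Average a model-record table over final layers
#'
#' Representational geometry varies across a network's layers; to avoid
#' relying on idiosyncrasies of a single layer, every metric and predictivity
#' value is averaged over the final `n_layers` representational layers of
#' each model (layer order = row order within a model), yielding one row per
#' model.
#'
#' @param table data.frame with columns `model_id`, `layer_id` and numeric
#'   metric/predictivity columns.
#' @param n_layers number of final layers to average (default 5; models with
#'   fewer layers raise an error).
#' @return a data.frame with one row per model.
#' @export
layer_average <- function(table, n_layers = 5L) {
  assert_that(all(c("model_id", "layer_id") %in% names(table)),
              "table needs model_id and layer_id columns", "domain_error")
  assert_that(!anyDuplicated(paste(table$model_id, table$layer_id)),
              "duplicate (model_id, layer_id) keys", "domain_error")
  num_cols <- names(table)[vapply(table, is.numeric, TRUE)]
  groups <- split(seq_len(nrow(table)), table$model_id)
  rows <- lapply(names(groups), function(m) {
    ix <- groups[[m]]
    if (length(ix) < n_layers)
      fg_stop(sprintf("model '%s' has %d layers < n_layers = %d",
                      m, length(ix), n_layers), "domain_error")
    ix <- utils::tail(ix, n_layers)
    out <- data.frame(model_id = m, stringsAsFactors = FALSE)
    for (col in num_cols) out[[col]] <- mean(table[[col]][ix])
    out
  })
  do.call(rbind, rows)
}

#' Correlation between a geometry metric and data predictivity
#'
#' Spearman rank correlation across models between a metric column and a
#' predictivity column, with a bootstrap standard deviation obtained by
#' resampling models with replacement.
#'
#' @param table per-model data.frame (see [layer_average()]).
#' @param metric,dataset column names.
#' @param n_bootstrap number of bootstrap resamples.
#' @param seed integer RNG seed.
#' @return list with `rho`, `bootstrap_sd`, `n_models`.
#' @export
metric_fit_correlation <- function(table, metric, dataset,
                                   n_bootstrap = 1000L, seed = 0L) {
  assert_that(all(c(metric, dataset) %in% names(table)),
              "metric/dataset column missing from table", "key_error")
  x <- table[[metric]]; y <- table[[dataset]]
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  assert_that(length(x) >= 5, "need at least 5 models with both values",
              "domain_error")
  if (stats::sd(x) == 0)
    fg_stop("metric is constant across models: correlation undefined",
            "undefined_score")
  rho <- stats::cor(x, y, method = "spearman")
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(b) {
      ix <- sample.int(length(x), replace = TRUE)
      if (stats::sd(x[ix]) == 0 || stats::sd(y[ix]) == 0) return(NA_real_)
      stats::cor(x[ix], y[ix], method = "spearman")
    }, 0)
  })
  list(rho = rho, bootstrap_sd = stats::sd(boots, na.rm = TRUE),
       n_models = length(x))
}

#' Held-out predictivity of a combined metric regression
#'
#' Regresses predictivity on one or more metric columns by ordinary least
#' squares over a random subset of models (default 80%), evaluates the
#' Spearman correlation between predicted and actual predictivity on the
#' held-out models, and averages over random splits.
#'
#' @param table per-model data.frame.
#' @param metrics character vector of metric column names.
#' @param dataset predictivity column name.
#' @param train_fraction fraction of models used for fitting (default 0.8).
#' @param n_splits number of random train/test splits (default 100).
#' @param seed integer RNG seed.
#' @return list with `mean_rho`, `split_rho` (per split), `n_models`.
#' @export
combined_metric_regression <- function(table, metrics, dataset,
                                       train_fraction = 0.8, n_splits = 100L,
                                       seed = 0L) {
  assert_that(all(c(metrics, dataset) %in% names(table)),
              "metric/dataset column missing from table", "key_error")
  df <- table[, c(metrics, dataset)]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  assert_that(n >= 10, "need at least 10 models", "domain_error")
  sds <- vapply(df[metrics], stats::sd, 0)
  if (any(sds == 0))
    fg_stop("constant metric column: regression rank-deficient",
            "regression_rank_error")
  X <- as.matrix(df[metrics])
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    fg_stop("collinear metric columns: regression rank-deficient",
            "regression_rank_error")
  y <- df[[dataset]]
  n_train <- max(2L, floor(train_fraction * n))
  rhos <- withr::with_seed(seed, {
    vapply(seq_len(n_splits), function(s) {
      tr <- sample.int(n, n_train)
      te <- setdiff(seq_len(n), tr)
      fit <- stats::lm.fit(cbind(1, X[tr, , drop = FALSE]), y[tr])
      yp <- drop(cbind(1, X[te, , drop = FALSE]) %*% fit$coefficients)
      stats::cor(yp, y[te], method = "spearman")
    }, 0)
  })
  list(mean_rho = mean(rhos), split_rho = rhos, n_models = n)
}
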