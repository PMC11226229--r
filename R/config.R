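#' Analysis configuration
#'
#' Bundles the knobs shared across metric and model-fit computations.
#'
#' @param pca_variance_threshold fraction in (0, 1] of cumulative explained
#'   variance used when selecting principal subspaces (default 0.9, i.e. the
#'   top components containing 90% of the variance).
#' @param encoding_n_components number of principal components a feature
#'   representation is projected onto before ridge encoding fits
#'   (default 300; capped at the matrix rank).
#' @param ridge_penalty_grid positive penalties searched by inner
#'   cross-validation in [encoding_fit()].
#' @param cv_folds number of cross-validation folds (>= 2).
#' @param seed integer seed for every stochastic step (default 0).
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(pca_variance_threshold = 0.9,
                            encoding_n_components = 300L,
                            ridge_penalty_grid = 10^seq(-3, 3),
                            cv_folds = 5L,
                            seed = 0L) {
  assert_that(is.numeric(pca_variance_threshold) &&
                pca_variance_threshold > 0 && pca_variance_threshold <= 1,
              "pca_variance_threshold must lie in (0, 1]", "config_error")
  assert_that(length(ridge_penalty_grid) >= 1 && all(ridge_penalty_grid > 0),
              "ridge_penalty_grid must be non-empty and positive", "config_error")
  assert_that(encoding_n_components >= 1, "encoding_n_components must be >= 1",
              "config_error")
  assert_that(cv_folds >= 2, "cv_folds must be >= 2", "config_error")
  structure(list(
    pca_variance_threshold = pca_variance_threshold,
    encoding_n_components = as.integer(encoding_n_components),
    ridge_penalty_grid = as.numeric(ridge_penalty_grid),
    cv_folds = as.integer(cv_folds),
    seed = as.integer(seed)
  ), class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Fixed schema: any subset of the fields of [analysis_config()]; missing
#' fields take their defaults.
#' @param path YAML file path.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path), "io_error")
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  extra <- setdiff(names(vals), known)
  assert_that(length(extra) == 0,
              sprintf("unknown config fields: %s", paste(extra, collapse = ", ")),
              "config_error")
  do.call(analysis_config, vals)
}

#' @rdname read_config
#' @param config an `analysis_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
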