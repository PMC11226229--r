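#' Configuration for the binary-feature simulation
#'
#' A population encodes `n_dims` binary features, each as a coefficient of +1
#' or -1 along its own axis.  All but two of the axes are mutually orthogonal
#' and orthogonal to the last two, which serve as decoder targets and whose
#' inner product equals `alignment` (0 = orthogonal/factorized code, 1 =
#' identical/collinear axes).  Isotropic Gaussian noise perturbs every point.
#'
#' @param n_dims number of binary features and of space dimensions (default
#'   10).
#' @param alignment cosine between the two target axes, in \[0, 1\].
#' @param noise_sd standard deviation of the isotropic Gaussian noise.
#' @param k_train training examples per sign and per target variable (K).
#' @param n_test held-out test points.
#' @param seed integer RNG seed.
#' @return object of class `binary_factor_config`.
#' @export
binary_factor_config <- function(n_dims = 10L, alignment = 0, noise_sd = 0.5,
                                 k_train = 2L, n_test = 200L, seed = 0L) {
  assert_that(n_dims >= 2, "n_dims must be >= 2", "domain_error")
  assert_that(alignment >= 0 && alignment <= 1,
              "alignment must lie in [0, 1]", "domain_error")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0", "domain_error")
  assert_that(k_train >= 1 && n_test >= 1, "k_train and n_test must be >= 1",
              "domain_error")
  structure(list(n_dims = as.integer(n_dims), alignment = alignment,
                 noise_sd = noise_sd, k_train = as.integer(k_train),
                 n_test = as.integer(n_test), seed = as.integer(seed)),
            class = "binary_factor_config")
}

#' Generate binary-feature simulation data
#'
#' Samples balanced training sets (exactly K positive and K negative
#' examples per target variable) and a random test set from the code
#' described in [binary_factor_config()].
#'
#' @param config a [binary_factor_config()].
#' @return a list of class `binary_factor_data`:
#'   * `train`: two elements (one per target variable), each `list(x, y)`
#'     with `2 * k_train` rows and labels in \{-1, +1\};
#'   * `test`: `list(x, y1, y2)` with `n_test` rows and both targets;
#'   * `ground_truth`: the axis matrix (rows = feature axes; rows 1 and 2
#'     are the targets), `alignment`, `noise_sd`.
#' @export
gen_binary_factor_data <- function(config) {
  stopifnot(inherits(config, "binary_factor_config"))
  n <- config$n_dims
  a <- config$alignment
  axes <- diag(n)
  axes[1, ] <- c(1, rep(0, n - 1))
  axes[2, ] <- c(a, sqrt(1 - a^2), rep(0, n - 2))
  withr::with_seed(config$seed, {
    sample_points <- function(F) {
      X <- F %*% axes
      if (config$noise_sd > 0)
        X <- X + matrix(stats::rnorm(length(X), sd = config$noise_sd),
                        nrow(X), ncol(X))
      X
    }
    rand_feats <- function(m) {
      matrix(sample(c(-1, 1), m * n, replace = TRUE), m, n)
    }
    train <- lapply(1:2, function(j) {
      F <- rand_feats(2L * config$k_train)
      F[, j] <- rep(c(1, -1), each = config$k_train)
      list(x = sample_points(F), y = F[, j])
    })
    Ft <- rand_feats(config$n_test)
    test <- list(x = sample_points(Ft), y1 = Ft[, 1], y2 = Ft[, 2])
  })
  structure(list(train = train, test = test,
                 ground_truth = list(axes = axes, alignment = a,
                                     noise_sd = config$noise_sd)),
            class = "binary_factor_data")
}

#' Configuration for augmentation-structured population responses
#'
#' Emulates, at the feature level, a stimulus set of `n_base_scenes` base
#' scenes each rendered at `n_levels` levels of each scene parameter
#' (canonically 100 scenes x 4 parameters x 10 levels = 4000 conditions).
#' Each parameter `p` owns a `dim`-dimensional latent subspace `B_p`; level
#' offsets are drawn in it with the configured total variance.  Pairwise
#' subspace alignment is controlled through the first principal angle: the
#' first basis vector of each parameter receives a `sqrt(alignment_p)`
#' component along one shared direction, so the pairwise cosine is
#' `sqrt(alignment_p * alignment_q)` (equal to the common value when all
#' alignments agree); remaining principal angles are 90 degrees.  Base-scene
#' identity occupies its own orthogonal subspace.  Level offsets are scaled
#' by `n_levels / (n_levels - 1)` so the package's n-denominator within-scene
#' variance estimator is unbiased for the configured variance.
#'
#' @param n_units number of features/units.
#' @param n_base_scenes number of base scenes (default 100).
#' @param n_levels levels per parameter per scene (default 10).
#' @param params named list (names from [SCENE_PARAMS]) of
#'   `list(dim =, var =, alignment =)` per parameter.
#' @param base_scene_variance total variance of base-scene latents.
#' @param scene_dim dimension of the base-scene subspace.
#' @param noise_sd isotropic Gaussian noise standard deviation.
#' @param seed integer RNG seed.
#' @return object of class `augmentation_sim_config`.
#' @export
augmentation_sim_config <- function(n_units = 60L, n_base_scenes = 100L,
                                    n_levels = 10L,
                                    params = default_sim_params(),
                                    base_scene_variance = 1,
                                    scene_dim = 5L,
                                    noise_sd = 0.02,
                                    seed = 0L) {
  assert_that(length(params) >= 1 && !is.null(names(params)),
              "params must be a named list", "domain_error")
  bad <- setdiff(names(params), SCENE_PARAMS)
  assert_that(length(bad) == 0,
              sprintf("unknown scene parameter(s): %s", paste(bad, collapse = ", ")),
              "vocabulary_error")
  dims <- vapply(params, function(p) p$dim, 0)
  aligns <- vapply(params, function(p) p$alignment, 0)
  assert_that(all(aligns >= 0 & aligns <= 1), "alignments must lie in [0, 1]",
              "domain_error")
  assert_that(n_levels >= 2, "n_levels must be >= 2", "domain_error")
  assert_that(base_scene_variance >= 0 && noise_sd >= 0,
              "variances must be non-negative", "domain_error")
  needed <- sum(dims) + scene_dim + (if (any(aligns > 0)) 1L else 0L)
  if (needed > n_units)
    fg_stop(sprintf("infeasible construction: %d dimensions needed but n_units = %d",
                    needed, n_units), "construction_error")
  structure(list(n_units = as.integer(n_units),
                 n_base_scenes = as.integer(n_base_scenes),
                 n_levels = as.integer(n_levels), params = params,
                 base_scene_variance = base_scene_variance,
                 scene_dim = as.integer(scene_dim),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "augmentation_sim_config")
}

#' @rdname augmentation_sim_config
#' @param dim,var,alignment defaults shared by all four parameters.
#' @export
default_sim_params <- function(dim = 5L, var = 1, alignment = 0) {
  stats::setNames(lapply(SCENE_PARAMS, function(p)
    list(dim = dim, var = var, alignment = alignment)), SCENE_PARAMS)
}

#' Generate augmentation-structured responses with known geometry
#'
#' @param config an [augmentation_sim_config()].
#' @return a list of class `labeled_dataset`: `responses`
#'   ([response_matrix()]), `design` (augmentation-mode
#'   [augmentation_design()]) and `ground_truth` (per-parameter orthonormal
#'   bases and true induced covariances, scene basis, latent variances,
#'   pairwise alignments, noise_sd).
#' @seealso [ground_truth_factorization()] to score the planted geometry.
#' @export
gen_augmentation_responses <- function(config) {
  stopifnot(inherits(config, "augmentation_sim_config"))
  p_names <- names(config$params)
  dims <- vapply(config$params, function(p) p$dim, 0)
  vars <- vapply(config$params, function(p) p$var, 0)
  aligns <- vapply(config$params, function(p) p$alignment, 0)
  L <- config$n_levels
  S <- config$n_base_scenes
  withr::with_seed(config$seed, {
    Q <- random_orthonormal(config$n_units)
    shared <- Q[, 1]
    col <- 2L
    bases <- list()
    for (i in seq_along(p_names)) {
      d <- dims[i]
      priv <- Q[, col:(col + d - 1), drop = FALSE]
      col <- col + d
      B <- priv
      if (aligns[i] > 0)
        B[, 1] <- sqrt(aligns[i]) * shared + sqrt(1 - aligns[i]) * priv[, 1]
      bases[[p_names[i]]] <- B
    }
    scene_basis <- Q[, col:(col + config$scene_dim - 1), drop = FALSE]
    centers <- matrix(stats::rnorm(S * config$scene_dim,
                                   sd = sqrt(config$base_scene_variance /
                                               config$scene_dim)),
                      S, config$scene_dim) %*% t(scene_basis)
    n_rows <- S * length(p_names) * L
    X <- matrix(0, n_rows, config$n_units)
    cid <- character(n_rows)
    scene_id <- character(n_rows)
    vparam <- character(n_rows)
    level <- integer(n_rows)
    r <- 1L
    # unbiasedness calibration for the n-denominator variance estimator
    var_scale <- L / (L - 1)
    for (s in seq_len(S)) {
      for (i in seq_along(p_names)) {
        p <- p_names[i]
        Z <- matrix(stats::rnorm(L * dims[i],
                                 sd = sqrt(var_scale * vars[i] / dims[i])),
                    L, dims[i])
        offs <- Z %*% t(bases[[p]])
        ix <- r:(r + L - 1L)
        X[ix, ] <- matrix(centers[s, ], L, config$n_units, byrow = TRUE) + offs
        cid[ix] <- sprintf("s%03d_%s_l%02d", s, p, 0:(L - 1))
        scene_id[ix] <- sprintf("s%03d", s)
        vparam[ix] <- p
        level[ix] <- 0:(L - 1)
        r <- r + L
      }
    }
    if (config$noise_sd > 0)
      X <- X + matrix(stats::rnorm(length(X), sd = config$noise_sd),
                      nrow(X), ncol(X))
  })
  responses <- response_matrix(X, condition_ids = cid)
  design <- augmentation_design(data.frame(
    condition_id = cid, base_scene_id = scene_id, varied_param = vparam,
    level = level, class_label = NA, stringsAsFactors = FALSE))
  true_covs <- lapply(seq_along(p_names), function(i)
    (vars[i] / dims[i]) * tcrossprod(bases[[p_names[i]]]))
  names(true_covs) <- p_names
  structure(list(
    responses = responses, design = design,
    ground_truth = list(param_bases = bases, scene_basis = scene_basis,
                        latent_variances = stats::setNames(vars, p_names),
                        alignments = stats::setNames(aligns, p_names),
                        true_covariances = true_covs,
                        noise_sd = config$noise_sd)
  ), class = "labeled_dataset")
}

#' Ground-truth covariance factorization of a generated dataset
#'
#' Evaluates the covariance-based factorization score on the *generating*
#' covariances of a [gen_augmentation_responses()] dataset, giving the value
#' the estimator should recover from data.
#'
#' @param ground_truth the `ground_truth` element of a `labeled_dataset`.
#' @param param the parameter to score.
#' @return a number in \[0, 1\].
#' @export
ground_truth_factorization <- function(ground_truth, param) {
  covs <- ground_truth$true_covariances
  assert_that(param %in% names(covs), "unknown parameter", "key_error")
  others <- setdiff(names(covs), param)
  assert_that(length(others) >= 1, "need at least 2 parameters", "domain_error")
  cov_other <- Reduce(`+`, covs[others]) / length(others)
  factorization_from_cov_pair(covs[[param]], cov_other)
}

#' Generate a class-structured population
#'
#' Draws class centers in a subspace whose first principal angle to the
#' within-class principal subspace has cosine `center_alignment` (0 =
#' orthogonal: class structure fully factorized from nuisance variation).
#' Within-class residuals share a common covariance with the given eigenvalue
#' spectrum.
#'
#' @param n_classes number of classes (>= 2).
#' @param n_per_class conditions per class (>= 2).
#' @param n_units features (>= 2).
#' @param center_spread standard deviation of class-center coordinates.
#' @param within_cov_spec eigenvalue spectrum (vector) of the within-class
#'   covariance.
#' @param center_alignment cosine in \[0, 1\] between the center subspace and
#'   the leading within-class axis.
#' @param seed integer RNG seed.
#' @return a list of class `labeled_dataset` with `responses`, a grouped-mode
#'   `design`, and `ground_truth` (bases and spectra).
#' @export
gen_class_dataset <- function(n_classes, n_per_class, n_units,
                              center_spread = 1,
                              within_cov_spec = rep(1, 3),
                              center_alignment = 0, seed = 0L) {
  assert_that(n_classes >= 2, "need at least 2 classes", "domain_error")
  assert_that(n_per_class >= 2,
              "n_per_class must be >= 2 (within-class variance undefined otherwise)",
              "domain_error")
  assert_that(n_units >= 2, "n_units must be >= 2", "domain_error")
  assert_that(center_alignment >= 0 && center_alignment <= 1,
              "center_alignment must lie in [0, 1]", "domain_error")
  k_w <- length(within_cov_spec)
  d_c <- min(n_classes - 1L, n_units - k_w)
  assert_that(d_c >= 1,
              "n_units too small for the requested within-class spectrum",
              "construction_error")
  withr::with_seed(seed, {
    Q <- random_orthonormal(n_units)
    W <- Q[, seq_len(k_w), drop = FALSE]
    Cfree <- Q[, (k_w + 1):(k_w + d_c), drop = FALSE]
    Cb <- Cfree
    if (center_alignment > 0)
      Cb[, 1] <- center_alignment * W[, 1] +
        sqrt(1 - center_alignment^2) * Cfree[, 1]
    centers <- matrix(stats::rnorm(n_classes * d_c, sd = center_spread),
                      n_classes, d_c) %*% t(Cb)
    n <- n_classes * n_per_class
    lab <- rep(sprintf("class%03d", seq_len(n_classes)), each = n_per_class)
    E <- matrix(stats::rnorm(n * k_w), n, k_w) %*%
      diag(sqrt(within_cov_spec), k_w) %*% t(W)
    X <- centers[rep(seq_len(n_classes), each = n_per_class), , drop = FALSE] + E
  })
  cid <- sprintf("%s_r%03d", lab, rep(seq_len(n_per_class), n_classes))
  responses <- response_matrix(X, condition_ids = cid)
  design <- augmentation_design(data.frame(
    condition_id = cid, base_scene_id = NA, varied_param = NA, level = NA,
    class_label = lab, stringsAsFactors = FALSE))
  structure(list(
    responses = responses, design = design,
    ground_truth = list(center_basis = Cb, within_basis = W,
                        within_cov_spec = within_cov_spec,
                        center_alignment = center_alignment)
  ), class = "labeled_dataset")
}

#' Generate movie-like frame responses
#'
#' Frames come in consecutive pairs.  Within-pair (local-in-time) differences
#' live in a "local" subspace whose first principal angle to the "global"
#' (across-pair) subspace has cosine `local_alignment`; pair centers live in
#' the global subspace.
#'
#' @param n_frames even number of frames (>= 4).
#' @param n_units number of features.
#' @param local_dim,global_dim subspace dimensions.
#' @param local_var,global_var total latent variances.
#' @param local_alignment cosine in \[0, 1\].
#' @param noise_sd isotropic noise standard deviation (default 0).
#' @param seed integer RNG seed.
#' @return a time-ordered [response_matrix()] with ground truth attached as
#'   attribute `"ground_truth"`.
#' @export
gen_movie_responses <- function(n_frames, n_units = 20L, local_dim = 1L,
                                global_dim = 1L, local_var = 1,
                                global_var = 1, local_alignment = 0,
                                noise_sd = 0, seed = 0L) {
  assert_that(n_frames %% 2 == 0 && n_frames >= 4,
              "n_frames must be even and >= 4", "domain_error")
  assert_that(local_alignment >= 0 && local_alignment <= 1,
              "local_alignment must lie in [0, 1]", "domain_error")
  needed <- local_dim + global_dim + (if (local_alignment > 0) 1L else 0L)
  assert_that(needed <= n_units, "subspace dimensions exceed n_units",
              "construction_error")
  n_pairs <- n_frames / 2L
  withr::with_seed(seed, {
    Q <- random_orthonormal(n_units)
    G <- Q[, seq_len(global_dim), drop = FALSE]
    Lfree <- Q[, (global_dim + 1):(global_dim + local_dim), drop = FALSE]
    Lb <- Lfree
    if (local_alignment > 0)
      Lb[, 1] <- local_alignment * G[, 1] +
        sqrt(1 - local_alignment^2) * Lfree[, 1]
    centers <- matrix(stats::rnorm(n_pairs * global_dim,
                                   sd = sqrt(global_var / global_dim)),
                      n_pairs, global_dim) %*% t(G)
    half <- matrix(stats::rnorm(n_pairs * local_dim,
                                sd = sqrt(local_var / local_dim)),
                   n_pairs, local_dim) %*% t(Lb)
    X <- matrix(0, n_frames, n_units)
    X[seq(1, n_frames, by = 2), ] <- centers + half
    X[seq(2, n_frames, by = 2), ] <- centers - half
    if (noise_sd > 0)
      X <- X + matrix(stats::rnorm(length(X), sd = noise_sd), n_frames, n_units)
  })
  out <- response_matrix(X, condition_ids = sprintf("frame%04d", seq_len(n_frames)))
  attr(out, "ground_truth") <- list(global_basis = G, local_basis = Lb,
                                    local_alignment = local_alignment)
  out
}

#' Fabricate a model-zoo record table
#'
#' Builds a synthetic table of model-layer metric and predictivity values
#' with a planted linear relationship, for validating the meta-analysis:
#' `predictivity = sum(weights * metrics) + noise`, metrics drawn standard
#' normal per model with small per-layer jitter.
#'
#' @param n_models number of models.
#' @param n_layers layers per model (default 5).
#' @param weights named numeric vector: the metric columns and their planted
#'   contributions to predictivity.
#' @param noise_sd noise on predictivity.
#' @param layer_jitter_sd per-layer jitter around each model's metric value.
#' @param dataset_id name of the predictivity column suffix.
#' @param seed integer RNG seed.
#' @return a data.frame with columns `model_id`, `layer_id`, one column per
#'   metric, and `predictivity_<dataset_id>`.
#' @export
gen_model_table <- function(n_models = 200L, n_layers = 5L,
                            weights = c(classification = 1, factorization = 1),
                            noise_sd = 0.5, layer_jitter_sd = 0.1,
                            dataset_id = "synthetic", seed = 0L) {
  assert_that(n_models >= 2 && n_layers >= 1, "need models and layers",
              "domain_error")
  metric_names <- names(weights)
  withr::with_seed(seed, {
    model_vals <- matrix(stats::rnorm(n_models * length(weights)),
                         n_models, length(weights),
                         dimnames = list(NULL, metric_names))
    pred_model <- drop(model_vals %*% weights) +
      stats::rnorm(n_models, sd = noise_sd)
    df <- do.call(rbind, lapply(seq_len(n_models), function(m) {
      jit <- matrix(stats::rnorm(n_layers * length(weights), sd = layer_jitter_sd),
                    n_layers, length(weights))
      vals <- sweep(jit, 2, model_vals[m, ], `+`)
      out <- data.frame(model_id = sprintf("model%04d", m),
                        layer_id = sprintf("layer%02d", seq_len(n_layers)),
                        stringsAsFactors = FALSE)
      for (j in seq_along(metric_names)) out[[metric_names[j]]] <- vals[, j]
      out[[paste0("predictivity_", dataset_id)]] <-
        pred_model[m] + stats::rnorm(n_layers, sd = layer_jitter_sd)
      out
    }))
  })
  df
}
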