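test_that("param_variance matches hand computations and the generator oracle", {
  # one scene, two levels at (0,0) and (2,0): deviations +-1 -> variance 1
  X <- response_matrix(rbind(c(0, 0), c(2, 0)), c("a", "b"))
  d <- augmentation_design(data.frame(
    condition_id = c("a", "b"), base_scene_id = "s1",
    varied_param = "background", level = 0:1, class_label = NA))
  expect_equal(param_variance(X, d, "background"), 1)
  # all levels identical -> zero
  X0 <- response_matrix(rbind(c(3, 1), c(3, 1)), c("a", "b"))
  expect_equal(param_variance(X0, d, "background"), 0)
  expect_error(param_variance(X, d, "lighting"), class = "factorgeom_key_error")
})

test_that("other-parameter subspace follows the cumulative-variance rule", {
  # scene averages with exact spectrum ratio (9, 1): threshold 0.9 keeps one
  # component, threshold 1 keeps the full rank
  n_sc <- 4
  z1 <- c(3, 3, -3, -3); z2 <- c(1, -1, 1, -1)
  blocks <- lapply(seq_len(n_sc), function(s)
    rbind(c(z1[s], z2[s], 1, 0), c(z1[s], z2[s], -1, 0)))
  X <- do.call(rbind, blocks)
  ids <- sprintf("c%04d", seq_len(2 * n_sc))
  d <- augmentation_design(data.frame(
    condition_id = ids, base_scene_id = rep(sprintf("s%04d", seq_len(n_sc)), each = 2),
    varied_param = "object_pose", level = rep(0:1, n_sc), class_label = NA))
  rm_ <- response_matrix(X, ids)
  ss90 <- other_param_subspace(rm_, d, "object_pose", 0.9)
  expect_equal(ncol(ss90$basis), 1)
  ss100 <- other_param_subspace(rm_, d, "object_pose", 1.0)
  expect_equal(ncol(ss100$basis), 2)
  expect_equal(max(abs(crossprod(ss90$basis) - 1)), 0, tolerance = 1e-8)
  # rank-0 averages -> degenerate error
  Xc <- response_matrix(rbind(c(0, 0, 1, 0), c(0, 0, -1, 0),
                              c(0, 0, 2, 0), c(0, 0, -2, 0)),
                        sprintf("c%d", 1:4))
  dc <- augmentation_design(data.frame(
    condition_id = sprintf("c%d", 1:4),
    base_scene_id = rep(c("s1", "s2"), each = 2),
    varied_param = "object_pose", level = rep(0:1, 2), class_label = NA))
  expect_error(other_param_subspace(Xc, dc, "object_pose"),
               class = "factorgeom_degenerate_subspace")
})

test_that("pca factorization matches the hand-projection example", {
  # other-subspace = span(e1); parameter deviations along (e1+e2)/sqrt(2)
  # -> half the variance projects -> factorization 0.5
  d <- two_param_construction(45)
  expect_equal(factorization_pca(d$responses, d$design, "background"), 0.5,
               tolerance = 1e-10)
  # fully orthogonal and fully contained limits
  expect_equal(factorization_pca(two_param_construction(90)$responses,
                                 two_param_construction(90)$design, "background"),
               1, tolerance = 1e-10)
  expect_equal(factorization_pca(two_param_construction(0)$responses,
                                 two_param_construction(0)$design, "background"),
               0, tolerance = 1e-10)
})

test_that("covariance factorization matches closed forms on rank-1 pairs", {
  u <- c(1, 0, 0); v45 <- c(1, 1, 0) / sqrt(2)
  expect_equal(factorization_from_cov_pair(tcrossprod(u), tcrossprod(u)), 0)
  expect_equal(factorization_from_cov_pair(tcrossprod(u), tcrossprod(c(0, 1, 0))), 1)
  expect_equal(factorization_from_cov_pair(tcrossprod(u), tcrossprod(v45)), 0.5,
               tolerance = 1e-12)
  expect_error(factorization_from_cov_pair(matrix(0, 2, 2), diag(2)),
               class = "factorgeom_undefined_score")
})

test_that("invariance follows 1 - var_param / var_all", {
  d <- two_param_construction(90)
  v <- param_variance(d$responses, d$design, "background")
  vall <- all_param_variance(d$responses, d$design)
  expect_equal(invariance(d$responses, d$design, "background"), 1 - v / vall)
  # var_param = 2, var_all = 8 -> 0.75, constructed directly
  X <- response_matrix(
    rbind(c(-sqrt(2), -sqrt(6)), c(sqrt(2), -sqrt(6)),
          c(-sqrt(2), sqrt(6)), c(sqrt(2), sqrt(6))),
    sprintf("c%d", 1:4))
  dd <- augmentation_design(data.frame(
    condition_id = sprintf("c%d", 1:4),
    base_scene_id = rep(c("s1", "s2"), each = 2),
    varied_param = "background", level = rep(0:1, 2), class_label = NA))
  expect_equal(param_variance(X, dd, "background"), 2)
  expect_equal(all_param_variance(X, dd), 8)
  expect_equal(invariance(X, dd, "background"), 0.75)
})

test_that("within-subspace invariance is consistent and improves under orthogonality", {
  # when the target structure spans the full feature space (noise makes the
  # deviations full rank), threshold 1 projects with the identity and the
  # score equals plain invariance
  full <- gen_augmentation_responses(augmentation_sim_config(
    n_units = 8, n_base_scenes = 10, n_levels = 6,
    params = stats::setNames(lapply(1:2, function(i)
      list(dim = 2, var = 1, alignment = 0.3)), c("background", "lighting")),
    scene_dim = 2, noise_sd = 0.2, seed = 31))
  expect_equal(
    invariance_within_subspace(full$responses, full$design, "background",
                               "lighting", threshold = 1.0),
    invariance(full$responses, full$design, "background"), tolerance = 1e-8)
  # orthogonal class construction: invariance inside the class subspace
  # is at least the raw invariance
  cls <- gen_class_dataset(6, 20, 20, center_spread = 1,
                           within_cov_spec = rep(0.5, 4),
                           center_alignment = 0, seed = 9)
  raw <- invariance(cls$responses, cls$design, "non_class")
  within <- invariance_within_subspace(cls$responses, cls$design,
                                       "non_class", "class")
  expect_gte(within, raw)
  expect_gt(within, 0.95)
})

test_that("dimensionality measures match their formulas", {
  # spectrum ratio (4, 1): participation ratio 25/17
  X <- rbind(c(2, 0), c(-2, 0), c(0, 1), c(0, -1),
             c(2, 0), c(-2, 0), c(0, 1), c(0, -1))
  rm_ <- response_matrix(X, sprintf("c%d", 1:8))
  expect_equal(dimensionality(rm_, "participation_ratio"), 25 / 17,
               tolerance = 1e-12)
  # spectrum ratio (9, 1): cumulative fraction hits 0.9 at one component
  X9 <- rbind(c(3, 0), c(-3, 0), c(0, 1), c(0, -1),
              c(3, 0), c(-3, 0), c(0, 1), c(0, -1))
  rm9 <- response_matrix(X9, sprintf("c%d", 1:8))
  expect_equal(dimensionality(rm9, "pc_count", 0.9), 1)
  expect_equal(dimensionality(rm9, "pc_count", 0.95), 2)
  # isotropic 5-d cloud: participation ratio = 5 for an exactly white sample
  set.seed(2)
  Y <- matrix(rnorm(400 * 5), 400, 5)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  Y <- Y %*% solve(chol(crossprod(Y) / nrow(Y)))
  expect_equal(dimensionality(response_matrix(Y, sprintf("c%d", 1:400)),
                              "participation_ratio"), 5, tolerance = 1e-8)
})

test_that("undefined scores raise typed errors instead of sentinels", {
  d <- two_param_construction(45)
  # zero parameter-induced variance
  X <- unclass(d$responses)
  bg <- d$design$varied_param == "background"
  # collapse each scene's background rows onto one point
  for (s in unique(d$design$base_scene_id)) {
    ix <- which(bg & d$design$base_scene_id == s)
    X[ix, ] <- matrix(X[ix[1], ], length(ix), ncol(X), byrow = TRUE)
  }
  rm0 <- response_matrix(X, condition_ids = condition_ids(d$responses))
  expect_error(factorization_pca(rm0, d$design, "background"),
               class = "factorgeom_undefined_score")
})

test_that("all scores are invariant under orthogonal transforms of features", {
  dat <- gen_augmentation_responses(augmentation_sim_config(
    n_units = 30, n_base_scenes = 12, n_levels = 5,
    params = stats::setNames(lapply(1:3, function(i)
      list(dim = 2, var = 1, alignment = 0.4)),
      c("background", "lighting", "object_pose")),
    scene_dim = 3, noise_sd = 0.05, seed = 13))
  Q <- random_rotation(30, seed = 2)
  rot <- rotate_responses(dat$responses, Q)
  for (p in c("background", "lighting")) {
    expect_equal(factorization_pca(rot, dat$design, p),
                 factorization_pca(dat$responses, dat$design, p),
                 tolerance = 1e-8)
    expect_equal(factorization_cov(rot, dat$design, p),
                 factorization_cov(dat$responses, dat$design, p),
                 tolerance = 1e-8)
    expect_equal(invariance(rot, dat$design, p),
                 invariance(dat$responses, dat$design, p), tolerance = 1e-8)
  }
  expect_equal(dimensionality(rot, "participation_ratio"),
               dimensionality(dat$responses, "participation_ratio"),
               tolerance = 1e-8)
})

test_that("factorization scores respect their [0, 1] bounds on random data", {
  for (seed in 1:5) {
    dat <- gen_augmentation_responses(augmentation_sim_config(
      n_units = 25, n_base_scenes = 8, n_levels = 4,
      params = stats::setNames(lapply(1:2, function(i)
        list(dim = 3, var = runif(1, 0.5, 2), alignment = runif(1))),
        c("background", "camera_viewpoint")),
      scene_dim = 2, noise_sd = 0.3, seed = seed))
    for (p in c("background", "camera_viewpoint")) {
      fp <- factorization_pca(dat$responses, dat$design, p)
      fc <- factorization_cov(dat$responses, dat$design, p)
      expect_true(fp >= 0 && fp <= 1)
      expect_true(fc >= 0 && fc <= 1)
      expect_lte(invariance(dat$responses, dat$design, p), 1)
    }
  }
})

test_that("scores ignore level labels but respond to scene grouping", {
  dat <- gen_augmentation_responses(augmentation_sim_config(
    n_units = 20, n_base_scenes = 8, n_levels = 4,
    params = stats::setNames(lapply(1:2, function(i)
      list(dim = 2, var = 1, alignment = 0.5)), c("background", "lighting")),
    scene_dim = 2, noise_sd = 0.1, seed = 21))
  d2 <- dat$design
  # permute level labels within each (scene, parameter) cell: levels are
  # exchangeable, so every score is unchanged
  withr::with_seed(1, {
    for (s in unique(d2$base_scene_id)) for (p in unique(d2$varied_param)) {
      ix <- which(d2$base_scene_id == s & d2$varied_param == p)
      d2$level[ix] <- sample(d2$level[ix])
    }
  })
  expect_equal(factorization_pca(dat$responses, d2, "background"),
               factorization_pca(dat$responses, dat$design, "background"))
  expect_equal(factorization_cov(dat$responses, d2, "background"),
               factorization_cov(dat$responses, dat$design, "background"))
})

test_that("movie scores behave at the constructed limits", {
  # constant within-pair movie: invariance 1, factorization undefined
  X <- rbind(c(1, 0), c(1, 0), c(0, 2), c(0, 2), c(3, 1), c(3, 1))
  mv <- response_matrix(X, sprintf("f%d", 1:6))
  expect_warning(out <- movie_factorization(mv, "pca"),
                 class = "factorgeom_undefined_score")
  expect_identical(out$invariance, 1)
  expect_true(is.na(out$factorization))
  # pair differences orthogonal to the pair-mean subspace: factorization 1
  mv0 <- gen_movie_responses(60, local_alignment = 0, seed = 8)
  expect_gt(movie_factorization(mv0, "pca")$factorization, 0.999)
  # intermediate alignment: 1 - cos^2 closed form, covariance variant
  mv5 <- gen_movie_responses(60, local_alignment = 0.5, seed = 8)
  expect_equal(movie_factorization(mv5, "cov")$factorization, 0.75,
               tolerance = 1e-10)
  expect_error(movie_factorization(response_matrix(X[1:2, ], c("a", "b"))),
               class = "factorgeom_domain_error")
})

test_that("geometry_scores aggregates every parameter of a design", {
  d <- two_param_construction(60)
  gs <- geometry_scores(d$responses, d$design)
  expect_setequal(gs$scores$param, c("background", "lighting"))
  expect_equal(gs$scores$factorization_cov[gs$scores$param == "background"],
               0.75, tolerance = 1e-10)
  expect_true(all(gs$scores$factorization_pca >= 0 &
                    gs$scores$factorization_pca <= 1))
})
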