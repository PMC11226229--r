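# Deterministic fixtures built in code.

# Two-parameter augmentation construction with a known angle theta between
# the parameter-of-interest axis u and the other-parameter axis v.  Scene
# centers are spread along v, so the other-parameter subspace is exactly
# span(v); level offsets are zero-mean so scene averages hit the centers
# exactly.  Both factorization variants of the "background" parameter equal
# 1 - cos^2(theta) in closed form.
two_param_construction <- function(theta_deg, n_scenes = 12, n_units = 10) {
  th <- theta_deg * pi / 180
  u <- c(1, rep(0, n_units - 1))
  v <- c(cos(th), sin(th), rep(0, n_units - 2))
  z <- seq(-1, 1, length.out = n_scenes)
  dl <- c(-1.5, -0.5, 0.5, 1.5)
  blocks <- lapply(seq_len(n_scenes), function(s) {
    ctr <- z[s] * v
    rbind(t(vapply(dl, function(d) ctr + d * u, numeric(n_units))),
          t(vapply(dl, function(d) ctr + d * v, numeric(n_units))))
  })
  X <- do.call(rbind, blocks)
  ids <- as.vector(vapply(seq_len(n_scenes), function(s)
    c(sprintf("s%02d_bg_l%d", s, seq_along(dl) - 1),
      sprintf("s%02d_li_l%d", s, seq_along(dl) - 1)), character(2 * length(dl))))
  df <- data.frame(
    condition_id = ids,
    base_scene_id = rep(sprintf("s%02d", seq_len(n_scenes)), each = 2 * length(dl)),
    varied_param = rep(rep(c("background", "lighting"), each = length(dl)), n_scenes),
    level = rep(c(seq_along(dl) - 1L, seq_along(dl) - 1L), n_scenes),
    class_label = NA, stringsAsFactors = FALSE)
  list(responses = response_matrix(X, condition_ids = ids),
       design = augmentation_design(df))
}

# Two classes in 2-D: centers (+-1, 0), within-class deviations (+-0.5)
# along the second axis.  Inter-class PC = e1, intra-class PC = e2, so the
# lesion rotation maps e1 to e2 and the centers to (0, +-1).
tiny_class_2d <- function() {
  X <- rbind(c(1, 0.5), c(1, -0.5), c(-1, 0.5), c(-1, -0.5))
  ids <- c("a1", "a2", "b1", "b2")
  lab <- c("A", "A", "B", "B")
  list(responses = response_matrix(X, condition_ids = ids),
       design = augmentation_design(data.frame(
         condition_id = ids, base_scene_id = NA, varied_param = NA,
         level = NA, class_label = lab, stringsAsFactors = FALSE)),
       labels = lab)
}

# A grouped-mode dataset with no class structure: pure isotropic noise with
# arbitrary (meaningless) class labels.
unstructured_class_data <- function(n_classes = 16, n_per_class = 4,
                                    n_units = 12, seed = 0) {
  n <- n_classes * n_per_class
  X <- withr::with_seed(seed, matrix(stats::rnorm(n * n_units), n, n_units))
  ids <- sprintf("c%03d", seq_len(n))
  lab <- rep(sprintf("k%02d", seq_len(n_classes)), each = n_per_class)
  list(responses = response_matrix(X, condition_ids = ids),
       design = augmentation_design(data.frame(
         condition_id = ids, base_scene_id = NA, varied_param = NA,
         level = NA, class_label = lab, stringsAsFactors = FALSE)))
}

random_rotation <- function(d, seed = 1) {
  withr::with_seed(seed, {
    M <- matrix(stats::rnorm(d * d), d, d)
    Q <- qr.Q(qr(M))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
  })
}

rotate_responses <- function(responses, Q) {
  response_matrix(unclass(responses) %*% Q,
                  condition_ids = condition_ids(responses))
}
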