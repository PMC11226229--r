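make_features <- function(n, p, seed) {
  response_matrix(withr::with_seed(seed, matrix(rnorm(n * p), n, p)),
                  condition_ids = sprintf("c%03d", seq_len(n)))
}

test_that("encoding fits recover realizable linear maps and stay honest on noise", {
  F <- make_features(80, 12, 1)
  B <- withr::with_seed(2, matrix(rnorm(12 * 6), 12, 6))
  Tg <- response_matrix(unclass(F) %*% B, condition_ids = condition_ids(F))
  cfg <- analysis_config(encoding_n_components = 12, cv_folds = 5, seed = 3)
  fit <- encoding_fit(F, Tg, cfg)
  expect_gt(fit$aggregate, 0.999)
  expect_true(all(fit$per_target_score > 0.999))
  # independent-noise targets: aggregate near zero (within 3 per-target SEs)
  Tn <- response_matrix(withr::with_seed(4, matrix(rnorm(80 * 6), 80, 6)),
                        condition_ids = condition_ids(F))
  fit0 <- encoding_fit(F, Tn, cfg)
  expect_lt(abs(fit0$aggregate), 3 / sqrt(80))
  # shuffled target rows (broken alignment) also kill the fit
  Tshuf <- response_matrix(unclass(Tg)[withr::with_seed(5, sample(80)), ],
                           condition_ids = condition_ids(F))
  expect_lt(abs(encoding_fit(F, Tshuf, cfg)$aggregate), 3 / sqrt(80))
})

test_that("encoding fits are invariant to orthogonal feature rotations", {
  F <- make_features(60, 10, 6)
  B <- withr::with_seed(7, matrix(rnorm(10 * 4), 10, 4))
  Tg <- response_matrix(unclass(F) %*% B + 0.5 *
                          withr::with_seed(8, matrix(rnorm(60 * 4), 60, 4)),
                        condition_ids = condition_ids(F))
  cfg <- analysis_config(encoding_n_components = 10, cv_folds = 5, seed = 3)
  Q <- random_rotation(10, seed = 10)
  f1 <- encoding_fit(F, Tg, cfg)
  f2 <- encoding_fit(rotate_responses(F, Q), Tg, cfg)
  expect_equal(f2$per_target_score, f1$per_target_score, tolerance = 1e-6)
})

test_that("constant targets are recorded missing and excluded from the aggregate", {
  F <- make_features(40, 6, 11)
  Y <- withr::with_seed(12, matrix(rnorm(40 * 3), 40, 3))
  Y[, 2] <- 1.5
  Tg <- response_matrix(Y, condition_ids = condition_ids(F))
  fit <- encoding_fit(F, Tg, analysis_config(encoding_n_components = 6,
                                             cv_folds = 4, seed = 1))
  expect_true(is.na(fit$per_target_score[2]))
  expect_false(is.na(fit$aggregate))
  other_ids <- response_matrix(withr::with_seed(13, matrix(rnorm(40 * 3), 40, 3)),
                               condition_ids = sprintf("d%03d", 1:40))
  expect_error(encoding_fit(F, other_ids),
               class = "factorgeom_alignment_error")
})

test_that("rdm similarity is rank-based, symmetric and order-stable", {
  F <- make_features(20, 8, 14)
  expect_equal(rdm_similarity(F, F), 1)
  scaled <- response_matrix(3 * unclass(F), condition_ids = condition_ids(F))
  expect_equal(rdm_similarity(F, scaled), 1)
  G <- make_features(20, 5, 15)
  expect_equal(rdm_similarity(F, G), rdm_similarity(G, F))
  # reordering both inputs identically leaves the score unchanged
  perm <- withr::with_seed(16, sample(20))
  Fp <- response_matrix(unclass(F)[perm, ], condition_ids = condition_ids(F)[perm])
  Gp <- response_matrix(unclass(G)[perm, ], condition_ids = condition_ids(G)[perm])
  expect_equal(rdm_similarity(Fp, Gp), rdm_similarity(F, G))
  expect_error(rdm_similarity(make_features(2, 3, 1), make_features(2, 3, 2)),
               class = "factorgeom_error")
})

test_that("a hand-built 3-condition pair gives Spearman -0.5 over its 3 pairs", {
  # similarities of a: (1, 0, 2) -> ranks (2, 1, 3); of b: (2, 6, 3) ->
  # ranks (1, 3, 2); Spearman = 1 - 6 * 6 / 24 = -0.5
  A <- response_matrix(rbind(c(1, 0), c(1, 1), c(0, 2)), c("x", "y", "z"))
  B <- response_matrix(rbind(c(2, 0), c(1, 0), c(3, 3)), c("x", "y", "z"))
  expect_equal(rdm_similarity(A, B), -0.5)
  s <- similarity_matrix(A)
  expect_equal(s, t(s))
})

test_that("behavioral signatures implement the two-alternative confusion rule", {
  P <- rbind(c(0.6, 0.2, 0.2), c(0.2, 0.6, 0.2))
  colnames(P) <- c("a", "b", "c")
  sig <- behavioral_signatures(P, c("a", "b"))
  expect_equal(unname(sig$i2[1, "b"]), 0.25)
  expect_true(is.na(sig$i2[1, "a"]))
  expect_equal(unname(sig$i1[1]), mean(c(1 - 0.25, 1 - 0.25)))
  # certainty on the true class: i2 all 0, i1 all 1
  P1 <- diag(3); colnames(P1) <- letters[1:3]
  sig1 <- behavioral_signatures(rbind(P1, P1[1, ]), c("a", "b", "c", "a"))
  expect_true(all(sig1$i2 == 0, na.rm = TRUE))
  expect_equal(unname(sig1$i1), rep(1, 4))
  # uniform probabilities: i2 all 0.5, i1 all 0.5
  Pu <- matrix(1 / 4, 3, 4, dimnames = list(NULL, letters[1:4]))
  sigu <- behavioral_signatures(Pu, c("a", "b", "c"))
  expect_true(all(sigu$i2 == 0.5, na.rm = TRUE))
  expect_equal(unname(sigu$i1), rep(0.5, 3))
  expect_error(behavioral_signatures(Pu * 2, c("a", "b", "c")),
               class = "factorgeom_domain_error")
})

test_that("signatures are equivariant under class relabeling", {
  P <- withr::with_seed(17, {
    M <- matrix(rexp(5 * 4), 5, 4); M / rowSums(M)
  })
  colnames(P) <- c("a", "b", "c", "d")
  truth <- c("a", "b", "c", "d", "a")
  sig <- behavioral_signatures(P, truth)
  perm <- c("c", "a", "d", "b")
  Pp <- P[, perm]
  sigp <- behavioral_signatures(Pp, truth)
  expect_equal(unname(sigp$i1), unname(sig$i1))
  expect_equal(unname(sigp$i2), unname(sig$i2[, perm]))
})

test_that("signature correlations match a direct formula oracle", {
  P1 <- rbind(c(0.7, 0.2, 0.1), c(0.5, 0.3, 0.2),
              c(0.1, 0.8, 0.1), c(0.25, 0.25, 0.5))
  P2 <- rbind(c(0.4, 0.4, 0.2), c(0.6, 0.2, 0.2),
              c(0.2, 0.6, 0.2), c(0.1, 0.2, 0.7))
  colnames(P1) <- colnames(P2) <- c("a", "b", "c")
  truth <- c("a", "a", "b", "c")
  s1 <- behavioral_signatures(P1, truth)
  s2 <- behavioral_signatures(P2, truth)
  got <- signature_correlation(s1, s2)
  # independent computation from the raw entries
  pearson <- function(x, y) {
    xm <- x - mean(x); ym <- y - mean(y)
    sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  }
  expect_equal(unname(got["i1_corr"]), pearson(s1$i1, s2$i1), tolerance = 1e-12)
  ok <- !is.na(s1$i2) & !is.na(s2$i2)
  expect_equal(unname(got["i2_corr"]), pearson(s1$i2[ok], s2$i2[ok]),
               tolerance = 1e-12)
  # identity and antisymmetry limits
  expect_equal(unname(signature_correlation(s1, s1)), c(1, 1))
  neg <- s1
  neg$i1 <- 2 * mean(s1$i1) - s1$i1
  neg$i2 <- 2 * mean(s1$i2, na.rm = TRUE) - s1$i2
  got_neg <- signature_correlation(s1, neg)
  expect_equal(unname(got_neg["i1_corr"]), -1, tolerance = 1e-12)
})
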