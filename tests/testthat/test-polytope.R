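six_means <- function(seed = 1, d = 4) {
  set.seed(seed)
  m <- matrix(rnorm(6 * d), 6, d,
              dimnames = list(behavior_classes(), NULL))
  structure(list(means = m, counts = rep(10L, 6), space = "stub"),
            class = "cd_class_means")
}

test_that("class means average labeled time points on the snippet clock", {
  # one 100 ms point per class: bins 1, 6, 11, ... map to snippets 1..6
  coords <- matrix(seq_len(12), 6, 2)
  emb <- stub_embedding(coords, kept_time_index = c(1L, 6L, 11L, 16L, 21L, 26L))
  labels <- factor(behavior_classes(), levels = behavior_classes())
  cm <- class_means(emb, labels)
  expect_equal(unname(cm$means), coords)
  # duplicated data leaves the means unchanged
  emb2 <- stub_embedding(rbind(coords, coords),
                         kept_time_index = c(1L, 6L, 11L, 16L, 21L, 26L,
                                             3L, 8L, 13L, 18L, 23L, 28L))
  expect_equal(class_means(emb2, labels)$means, cm$means)
  expect_error(class_means(emb, factor(rep("step", 6))), "class: turn")
})

test_that("rank concordance matches hand enumeration and brute force", {
  m <- six_means(3)
  Dv <- class_distance_matrix(m)
  expect_equal(unname(rank_concordance(Dv, Dv)), rep(5L, 6))
  # swapping one adjacent rank pair costs 2 matches for the affected class
  Dw <- Dv
  i <- "step"
  ord <- names(sort(Dv[i, setdiff(rownames(Dv), i)]))
  a <- ord[1]; b <- ord[2]
  Dw[i, a] <- Dv[i, b]; Dw[i, b] <- Dv[i, a]
  Dw[a, i] <- Dw[i, a]; Dw[b, i] <- Dw[i, b]
  s <- rank_concordance(Dv, Dw)
  expect_equal(unname(s[i]), 3L)
  # brute-force oracle on random matrices
  set.seed(9)
  for (trial in 1:5) {
    D1 <- class_distance_matrix(six_means(trial * 11))
    D2 <- class_distance_matrix(six_means(trial * 13 + 1))
    s_pkg <- rank_concordance(D1, D2)
    for (cl in rownames(D1)) {
      others <- setdiff(rownames(D1), cl)
      r1 <- rank(D1[cl, others], ties.method = "first")
      r2 <- rank(D2[cl, others], ties.method = "first")
      expect_equal(unname(s_pkg[cl]), sum(r1 == r2))
    }
  }
})

test_that("the exhaustive rank null has the documented size and mean", {
  null <- rank_null_distribution(6L)
  expect_equal(null$n_perms, 120L)
  expect_equal(null$n_pairs, 7260L)
  expect_length(null$s_boot, 7260L)
  # mean fixed points over ordered pairs (incl. self) is exactly 1
  total_ordered <- 2 * sum(null$s_boot) - 120L * 5L
  expect_equal(total_ordered / (120L * 120L), 1)
  null5 <- rank_null_distribution(5L)
  expect_equal(null5$n_perms, 24L)
  expect_equal(null5$n_pairs, 300L)
  # concordant observed values are extreme against the null
  expect_lt(rank_ks_test(rep(5L, 50), 6L)$p.value, 1e-6)
})

test_that("Jeffries-Matusita distance matches a loop-written formula", {
  D1 <- class_distance_matrix(six_means(2))
  D2 <- class_distance_matrix(six_means(4))
  acc <- 0
  for (i in 1:6) for (j in 1:6)
    acc <- acc + (sqrt(D1[i, j]) - sqrt(D2[i, j]))^2
  expect_equal(jm_distance(D1, D2), sqrt(acc), tolerance = 1e-12)
  expect_equal(jm_distance(D1, D1), 0)
})

test_that("a rigid transform of the same polytope is maximally similar", {
  v <- six_means(5)
  ang <- 0.8
  Q <- diag(4); Q[1:2, 1:2] <- matrix(c(cos(ang), sin(ang),
                                        -sin(ang), cos(ang)), 2)
  w <- v
  w$means <- sweep(2.2 * v$means %*% Q, 2, c(1, -2, 0.5, 3), `+`)
  r <- jm_similarity_test(v, w)
  expect_lt(r$d_jm, 1e-8)
  expect_equal(r$p_value, 1 / 720)
  expect_equal(r$n_perm, 720L)
  expect_equal(unname(r$s), rep(5L, 6))
  # excluding rest shrinks the null to 5! permutations
  r5 <- jm_similarity_test(v, w, exclude_rest = TRUE)
  expect_equal(r5$n_perm, 120L)
  expect_equal(r5$p_value, 1 / 120)
  expect_error(jm_similarity_test(v$means[1:2, ], v$means[1:2, ]), "fewer")
})

test_that("label-permuted polytopes have p uniform on the 1/720 grid", {
  set.seed(17)
  v <- six_means(6)
  ps <- replicate(40, {
    w <- six_means(sample.int(1e6, 1))
    jm_similarity_test(v, w)$p_value
  })
  expect_true(all(abs(ps * 720 - round(ps * 720)) < 1e-9))
  expect_true(all(ps > 0 & ps <= 1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("the JM test direction matters and is reproducible", {
  v <- six_means(7); w <- six_means(8)
  r_vw <- jm_similarity_test(v, w)
  r_wv <- jm_similarity_test(w, v)
  expect_identical(r_vw$p_value, jm_similarity_test(v, w)$p_value)
  # Procrustes maps the second argument onto the first: not symmetric
  expect_false(isTRUE(all.equal(r_vw$d_jm, r_wv$d_jm)))
})

test_that("the internal Procrustes engine agrees with vegan's", {
  set.seed(19)
  X <- matrix(rnorm(24), 6); Y <- matrix(rnorm(24), 6)
  fit <- crossdecode:::.procrustes_fit(X, Y)
  p <- vegan::procrustes(X, Y, symmetric = FALSE)
  Yhat_vegan <- sweep(p$scale * Y %*% p$rotation, 2, p$translation, `+`)
  expect_equal(fit$Yhat, Yhat_vegan, tolerance = 1e-10)
})

test_that("somatotopy shuffling is deterministic and refuses unknown regions", {
  v <- six_means(9, d = 10); w <- six_means(10, d = 10)
  reg <- rep(c("forelimb", "hindlimb"), each = 5)
  r1 <- somatotopy_shuffle_test(v, w, reg, reg, n_perm = 20L, seed = 4L)
  r2 <- somatotopy_shuffle_test(v, w, reg, reg, n_perm = 20L, seed = 4L)
  expect_identical(r1$p_values, r2$p_values)
  expect_true(all(r1$p_values >= 1 / 720 & r1$p_values <= 1))
  expect_error(somatotopy_shuffle_test(v, w, rep("unknown", 10), reg,
                                       n_perm = 5L),
               "region labels required")
  expect_message(
    somatotopy_shuffle_test(v, w, c("a", rep("b", 9)), reg, n_perm = 2L,
                            seed = 1L),
    "single unit")
})
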