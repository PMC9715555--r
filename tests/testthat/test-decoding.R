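test_that("class splits enumerate alignment/decoding partitions", {
  s4 <- class_splits(4L)
  s3 <- class_splits(3L)
  expect_length(s4, 15L)
  expect_length(s3, 20L)
  expect_error(class_splits(2L), "3, 4 or 5")
  for (sp in s4) {
    expect_length(intersect(sp$alignment, sp$decoding), 0L)
    expect_setequal(c(sp$alignment, sp$decoding), behavior_classes())
  }
  # every class appears in exactly C(5, n_align - 1) alignment sets
  for (cl in behavior_classes()) {
    expect_equal(sum(vapply(s4, function(s) cl %in% s$alignment, logical(1))),
                 choose(5, 3))
    expect_equal(sum(vapply(s3, function(s) cl %in% s$alignment, logical(1))),
                 choose(5, 2))
  }
})

test_that("feature windows have 81 smoothed bins per unit", {
  ses <- tiny_session()
  fw <- feature_windows(ses, stride_bins = 50L)
  expect_equal(ncol(fw$x), 81L * nrow(ses$units))
  expect_equal(levels(fw$y), c("stance", "swing"))
  # smoothing kernel is normalized: window mass ~ spike counts
  bins <- bin_spikes(ses, 0.01)
  total_sm <- sum(fw$x[1, 1:81])
  total_raw <- sum(bins[1, (fw$centers[1] - 40):(fw$centers[1] + 40)])
  expect_lt(abs(total_sm - total_raw), max(1, 0.2 * total_raw) + 2)
})

test_that("mean per-class accuracy equals the mean of the recalls", {
  set.seed(3)
  truth <- sample(c("a", "b", "c"), 300, replace = TRUE,
                  prob = c(0.6, 0.3, 0.1))
  pred <- sample(c("a", "b", "c"), 300, replace = TRUE)
  acc <- mean_per_class_accuracy(pred, truth)
  recalls <- vapply(c("a", "b", "c"),
                    function(cl) mean(pred[truth == cl] == cl), numeric(1))
  expect_equal(acc, mean(recalls))
  conf <- table(truth, pred)
  expect_equal(acc, mean(diag(conf) / rowSums(conf)))
})

test_that("the MLP learns a separable problem and respects its seed", {
  set.seed(5)
  n <- 400L
  x <- matrix(rnorm(n * 4), n)
  y <- factor(ifelse(x[, 1] + 0.5 * x[, 2] > 0, "A", "B"))
  idx <- sample(n)
  tr <- idx[1:280]; va <- idx[281:340]; te <- idx[341:400]
  fit <- mlp_fit(x[tr, ], y[tr], x[va, ], y[va], hidden = c(32L, 16L),
                 dropout = 0, lr = 1e-2, max_epochs = 150L, seed = 7L)
  acc <- mean_per_class_accuracy(predict(fit, x[te, ]), y[te])
  expect_gt(acc, 0.9)
  fit2 <- mlp_fit(x[tr, ], y[tr], x[va, ], y[va], hidden = c(32L, 16L),
                  dropout = 0, lr = 1e-2, max_epochs = 150L, seed = 7L)
  expect_identical(fit$W, fit2$W)
  p <- predict(fit, x[te, ], type = "prob")
  expect_equal(rowSums(p), rep(1, 60), tolerance = 1e-12)
})

test_that("Procrustes alignment recovers planted transforms", {
  set.seed(9)
  src <- matrix(rnorm(16), 4, dimnames = list(c("step", "turn", "drink",
                                                "groom"), NULL))
  tf <- procrustes_align(src, src)
  expect_lt(tf$residual, 1e-10)
  ang <- 1.1
  Q <- diag(4); Q[c(1, 3), c(1, 3)] <- matrix(c(cos(ang), sin(ang),
                                                -sin(ang), cos(ang)), 2)
  tgt <- sweep(src %*% Q / 1.7, 2, c(0.3, -0.2, 0.1, 0), `+`)
  rownames(tgt) <- rownames(src)
  tf2 <- procrustes_align(src, tgt)
  expect_lt(tf2$residual, 1e-8)
  expect_equal(tf2$scale, 1.7, tolerance = 1e-6)
  expect_equal(apply_alignment(tf2, tgt), src, tolerance = 1e-8,
               ignore_attr = TRUE)
  # orthogonality and least-squares optimality
  expect_equal(crossprod(tf2$rotation), diag(4), tolerance = 1e-8)
  noisy <- tgt + matrix(rnorm(16, 0, 0.1), 4)
  rownames(noisy) <- rownames(src)
  tf3 <- procrustes_align(src, noisy)
  expect_lte(tf3$residual, sqrt(sum((noisy - src)^2)) + 1e-12)
  # matches the independent closed-form oracle
  oracle <- oracle_procrustes(src, noisy)
  expect_equal(apply_alignment(tf3, noisy), oracle$Yhat, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(procrustes_align(src[1:2, ], tgt[1:2, ]), "underdetermined")
})

test_that("cross-session decoding keeps alignment and decoding sets apart", {
  set.seed(11)
  centers <- matrix(rnorm(24, sd = 3), 6, 4)
  mk <- function(shift) {
    n_snip <- 120L
    labels <- factor(sample(behavior_classes(), n_snip, replace = TRUE),
                     levels = behavior_classes())
    idx <- seq_len(n_snip * 5L)
    lab10 <- rep(as.integer(labels), each = 5L)
    coords <- centers[lab10, ] + matrix(rnorm(length(lab10) * 4, 0, 0.4),
                                        ncol = 4) + shift
    list(embedding = stub_embedding(coords, kept_time_index = idx),
         labels = labels)
  }
  a <- mk(0); b <- mk(1.5)
  sp <- class_splits(4L)[[1]]
  r <- cross_session_decode(a, b, sp, seed = 3L, n_rep = 3L)
  expect_true(r$audit$disjoint)
  expect_gt(r$accuracy_pct, 90)   # same centers: transfer is easy
  expect_equal(r$accuracy_pct, mean(r$recalls_pct), tolerance = 1e-9)
  r2 <- cross_session_decode(a, b, sp, seed = 3L, n_rep = 3L)
  expect_identical(r$accuracy_pct, r2$accuracy_pct)
  # a missing decoding class skips the split
  b_missing <- b
  lv <- b_missing$labels
  lv[lv == sp$decoding[1]] <- sp$decoding[2]
  b_missing$labels <- factor(as.character(lv), levels = behavior_classes())
  expect_message(r3 <- cross_session_decode(a, b_missing, sp, seed = 3L),
                 "skipped")
  expect_null(r3)
})

test_that("shuffled labels decode at chance", {
  set.seed(13)
  n_snip <- 240L
  coords <- matrix(rnorm(n_snip * 5L * 6L), ncol = 6L)
  emb <- stub_embedding(coords, kept_time_index = seq_len(n_snip * 5L))
  labels <- factor(sample(behavior_classes(), n_snip, replace = TRUE),
                   levels = behavior_classes())
  r <- behavior_decoder(emb, labels, seed = 2L, dims = 6L,
                        hidden = c(16L, 16L), max_epochs = 10L)
  # six-class chance is 16.67%; allow a generous Monte-Carlo band
  expect_lt(r$accuracy_pct, 28)
  expect_gt(r$accuracy_pct, 6)
  expect_equal(r$n_runs, 4L)
})

test_that("the generalization matrix averages ordered session pairs", {
  set.seed(15)
  mk <- function() {
    n_snip <- 100L
    labels <- factor(sample(behavior_classes(), n_snip, replace = TRUE),
                     levels = behavior_classes())
    centers <- matrix(rnorm(24, sd = 3), 6, 4)
    lab10 <- rep(as.integer(labels), each = 5L)
    coords <- centers[lab10, ] + matrix(rnorm(length(lab10) * 4, 0, 0.5),
                                        ncol = 4)
    list(embedding = stub_embedding(coords), labels = labels)
  }
  sessions <- list(s1 = mk(), s2 = mk())
  gm <- generalization_matrix(sessions, splits = class_splits(4L)[1:2],
                              seed = 5L, n_rep = 2L)
  expect_equal(dim(gm$matrix), c(2L, 2L))
  expect_false(anyNA(gm$matrix))
  expect_equal(unname(gm$generalization_incl_diag),
               unname(rowMeans(gm$matrix)))
  off <- gm$matrix; diag(off) <- NA
  expect_equal(unname(gm$generalization_off_diag),
               unname(rowMeans(off, na.rm = TRUE)))
})
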