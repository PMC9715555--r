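#' All splits of the six classes into alignment and decoding sets
#'
#' @param n_align Size of the alignment set (3, 4 or 5); the decoding set
#'   is the complement. 4 gives 15 splits, 3 gives 20.
#' @return List of lists with elements `alignment` and `decoding`
#'   (character vectors), in canonical order.
#' @export
class_splits <- function(n_align) {
  if (!n_align %in% 3:5) stop("n_align must be 3, 4 or 5")
  combs <- utils::combn(CLASSES, n_align)
  lapply(seq_len(ncol(combs)), function(j)
    list(alignment = combs[, j], decoding = setdiff(CLASSES, combs[, j])))
}

#' Smoothed spike-count feature windows for paw-state decoding
#'
#' For each sampled time point, the features are every unit's
#' Gaussian-smoothed (sigma 20 ms) 10 ms spike counts in a +/- 400 ms
#' window: 81 bins per unit. The target is the swing-stance status of one
#' paw at the window center.
#'
#' @param session A `cd_session`.
#' @param paw Paw whose status is decoded (default `"front-right"`).
#' @param stride_bins Sampling stride between window centers, in 10 ms
#'   bins (default 10, i.e. one sample per 100 ms).
#' @param sigma_ms Gaussian smoothing width (default 20 ms).
#' @param threshold Swing threshold, mm per 10 ms.
#' @return List: `x` (samples x `81 * n_units`), `y` (factor
#'   stance/swing), `centers` (10 ms bin index of each sample).
#' @export
feature_windows <- function(session, paw = "front-right", stride_bins = 10L,
                            sigma_ms = 20, threshold = 0.3) {
  paw <- match.arg(paw, PAWS)
  bins <- bin_spikes(session, 0.01)
  sm <- t(apply(bins, 1, gaussian_smooth, sd_bins = sigma_ms / 10))
  status <- as.integer(binarize_paw(session$velocity[, paw], threshold, paw))
  n <- ncol(bins)
  centers <- seq(41L, n - 40L, by = stride_bins)
  nu <- nrow(bins)
  x <- matrix(0, length(centers), nu * 81L)
  for (ci in seq_along(centers)) {
    w <- sm[, (centers[ci] - 40L):(centers[ci] + 40L), drop = FALSE]
    x[ci, ] <- as.vector(t(w))
  }
  list(x = x,
       y = factor(c("stance", "swing")[status[centers] + 1L],
                  levels = c("stance", "swing")),
       centers = centers)
}

.report <- function(pred, truth, extra = list()) {
  truth <- as.character(truth); pred <- as.character(pred)
  cls <- sort(unique(truth))
  recalls <- vapply(cls, function(cl) 100 * mean(pred[truth == cl] == cl),
                    numeric(1))
  conf <- table(truth = factor(truth, cls), pred = factor(pred, cls))
  c(list(accuracy_pct = mean(recalls), recalls_pct = recalls,
         confusion = conf), extra)
}

#' Within-session swing-stance decoder
#'
#' Feed-forward classifier on [feature_windows()] inputs with
#' class-weighted loss and early stopping (70/15/15 stratified
#' train/validation/test split), plus a ridge logistic-regression baseline
#' with 3-fold cross-validation of the regularization strength fitted on
#' the concatenated training and validation sets. Accuracies are mean
#' per-class (chance 50%).
#'
#' @param session A `cd_session`.
#' @param seed Integer seed (split, network initialization, baseline CV).
#' @param paw Decoded paw.
#' @param hidden,dropout,lr,max_epochs Network configuration (defaults
#'   sized for desk-scale sessions; see [mlp_fit()]).
#' @param stride_bins Feature sampling stride (10 ms bins).
#' @return Decoding report: `accuracy_pct`, `recalls_pct`, `confusion`,
#'   `baseline_accuracy_pct`, `n_samples`.
#' @export
swing_decoder <- function(session, seed = 1L, paw = "front-right",
                          hidden = c(128L, 64L), dropout = 0.5, lr = 1e-3,
                          max_epochs = 60L, stride_bins = 10L) {
  fw <- feature_windows(session, paw, stride_bins = stride_bins)
  if (nlevels(droplevels(fw$y)) < 2L)
    stop("paw status is constant over the sampled windows")
  n <- length(fw$y)
  split <- with_seed(seed, {
    part <- rep("train", n)
    for (cl in levels(fw$y)) {   # stratified 70/15/15
      ix <- which(fw$y == cl)
      ix <- ix[sample.int(length(ix))]
      n_val <- max(1L, round(0.15 * length(ix)))
      part[ix[seq_len(n_val)]] <- "val"
      part[ix[n_val + seq_len(n_val)]] <- "test"
    }
    part
  })
  tr <- split == "train"; va <- split == "val"; te <- split == "test"
  fit <- mlp_fit(fw$x[tr, ], fw$y[tr], fw$x[va, ], fw$y[va],
                 hidden = hidden, dropout = dropout, lr = lr,
                 max_epochs = max_epochs, seed = seed)
  pred <- predict(fit, fw$x[te, ])
  # ridge logistic baseline on train + validation
  trv <- tr | va
  wts <- as.numeric(1 / (table(fw$y[trv])[fw$y[trv]]))
  base <- with_seed(seed + 1L,
    glmnet::cv.glmnet(fw$x[trv, ], fw$y[trv], family = "binomial",
                      alpha = 0, nfolds = 3, weights = wts))
  bpred <- stats::predict(base, fw$x[te, ], s = "lambda.min", type = "class")
  rep <- .report(pred, fw$y[te],
                 list(baseline_accuracy_pct =
                        100 * mean_per_class_accuracy(bpred, fw$y[te]),
                      n_samples = n, best_epoch = fit$best_epoch))
  rep
}

# per-sample feature construction for the six-class decoder: 7 consecutive
# 100 ms bins (snippet's five plus one flank each side) x first `dims`
# embedding dimensions, flattened. Bins dropped by the activity filter are
# imputed from the nearest kept bin inside the window; snippets with fewer
# than `min_kept` of their 7 bins kept are dropped.
.behavior_samples <- function(embedding, labels, dims = 10L, min_kept = 3L) {
  dims <- min(dims, ncol(embedding$coords))
  coords <- embedding$coords[, seq_len(dims), drop = FALSE]
  pos <- match(seq_len(max(embedding$kept_time_index)),
               embedding$kept_time_index)
  keep_s <- which(as.character(labels) %in% CLASSES)
  feats <- vector("list", length(keep_s))
  ok <- logical(length(keep_s))
  for (si in seq_along(keep_s)) {
    s <- keep_s[si]
    binrange <- ((s - 1L) * 5L):((s * 5L) + 1L)   # 7 bins, centered
    if (binrange[1] < 1L || binrange[7] > length(pos)) next
    rows <- pos[binrange]
    present <- which(!is.na(rows))
    if (length(present) < min_kept) next
    if (anyNA(rows)) {
      for (m in which(is.na(rows)))
        rows[m] <- rows[present[which.min(abs(present - m))]]
    }
    feats[[si]] <- as.vector(coords[rows, ])
    ok[si] <- TRUE
  }
  list(x = do.call(rbind, feats[ok]),
       y = factor(as.character(labels)[keep_s[ok]], levels = CLASSES),
       snippet = keep_s[ok])
}

#' Six-class behavior decoder on embedded population activity
#'
#' Classifies the behavior of each labeled 500 ms snippet from the first
#' `dims` embedding dimensions in seven consecutive 100 ms bins centered on
#' the snippet. Features are min-max normalized with statistics from the
#' training folds only. The data is split into four equal parts; four runs
#' each train on two parts, early-stop on one and test on the fourth, and
#' the report averages the four test folds (chance 16.67%).
#'
#' @param embedding A `cd_embedding` with at least `dims` usable
#'   dimensions.
#' @param labels Snippet label factor.
#' @param seed Integer seed.
#' @param dims Embedding dimensions used (default 10).
#' @param hidden,dropout,lr,max_epochs Network configuration.
#' @return Decoding report averaged over the four folds: `accuracy_pct`,
#'   `recalls_pct`, `fold_accuracies_pct`, pooled `confusion`, `n_samples`.
#' @export
behavior_decoder <- function(embedding, labels, seed = 1L, dims = 10L,
                             hidden = c(200L, 200L, 200L), dropout = 0.25,
                             lr = 1e-3, max_epochs = 60L) {
  bs <- .behavior_samples(embedding, labels, dims)
  y <- droplevels(bs$y)
  if (any(table(y) < 4L))
    warning("a class has fewer than 4 samples; folds may miss it")
  n <- length(y)
  fold <- with_seed(seed, sample(rep_len(1:4, n)))
  preds <- vector("list", 4L)
  truths <- vector("list", 4L)
  accs <- numeric(4L)
  for (r in 1:4) {
    te <- fold == r
    va <- fold == (r %% 4L) + 1L
    tr <- !(te | va)
    lo <- apply(bs$x[tr, , drop = FALSE], 2, min)
    hi <- apply(bs$x[tr, , drop = FALSE], 2, max)
    rng <- pmax(hi - lo, 1e-12)
    nx <- function(m) sweep(sweep(m, 2, lo), 2, rng, `/`)
    fit <- mlp_fit(nx(bs$x[tr, , drop = FALSE]), y[tr],
                   nx(bs$x[va, , drop = FALSE]), y[va],
                   hidden = hidden, dropout = dropout, lr = lr,
                   max_epochs = max_epochs, seed = seed + r)
    preds[[r]] <- predict(fit, nx(bs$x[te, , drop = FALSE]))
    truths[[r]] <- y[te]
    accs[r] <- 100 * mean_per_class_accuracy(preds[[r]], y[te])
  }
  rep <- .report(unlist(lapply(preds, as.character)),
                 unlist(lapply(truths, as.character)),
                 list(fold_accuracies_pct = accs, n_samples = n,
                      n_runs = 4L))
  rep$accuracy_pct <- mean(accs)
  rep
}

#' Procrustes alignment of two embeddings from class means
#'
#' Least-squares Procrustes transform (translation, scaling, orthogonal
#' matrix including reflection) mapping the target session's alignment-set
#' class means onto the source session's, in a shared low dimensionality
#' (4 by default, to avoid underdetermination with 3-4 alignment classes).
#' Both embeddings are expected min-max normalized to `[0, 1]` per
#' dimension over all their time points before the means are taken.
#'
#' @param source_means,target_means Matrices (alignment classes x dims)
#'   of class means, identical row order.
#' @return A `cd_alignment`: `rotation` (orthogonal, `QtQ = I` to 1e-8),
#'   `scale`, `translation`, `classes`, `residual`.
#' @export
procrustes_align <- function(source_means, target_means) {
  X <- as.matrix(source_means); Y <- as.matrix(target_means)
  stopifnot(identical(rownames(X), rownames(Y)), ncol(X) == ncol(Y))
  if (nrow(X) < 3L) stop("fewer than 3 alignment classes: underdetermined")
  p <- vegan::procrustes(X, Y, symmetric = FALSE)
  Q <- p$rotation
  if (max(abs(crossprod(Q) - diag(ncol(Q)))) > 1e-8)
    stop("Procrustes rotation is not orthogonal")
  Yhat <- sweep(p$scale * Y %*% Q, 2, p$translation, `+`)
  structure(list(rotation = Q, scale = p$scale,
                 translation = as.numeric(p$translation),
                 classes = rownames(X),
                 residual = sqrt(sum((Yhat - X)^2))),
            class = "cd_alignment")
}

#' Apply a fitted alignment transform to points
#'
#' @param transform A `cd_alignment`.
#' @param points Points x dims matrix in the target session's space.
#' @return Transformed points in the source session's space.
#' @export
apply_alignment <- function(transform, points) {
  sweep(transform$scale * as.matrix(points) %*% transform$rotation, 2,
        transform$translation, `+`)
}

# 100 ms time-point labels for an embedding (snippet label inherited)
.point_labels <- function(embedding, labels) {
  snip <- (embedding$kept_time_index - 1L) %/% 5L + 1L
  factor(as.character(labels)[snip], levels = CLASSES)
}

.norm01 <- function(m) {
  lo <- apply(m, 2, min); hi <- apply(m, 2, max)
  sweep(sweep(m, 2, lo), 2, pmax(hi - lo, 1e-12), `/`)
}

#' Cross-session / cross-subject decoding with manifold alignment
#'
#' Aligns the test session's embedding onto the training session's with a
#' Procrustes transform fitted only on the alignment-set class means (the
#' decoding-set samples are never touched during fitting; the returned
#' `audit` records the index sets). An RBF-kernel SVM (kernel scale 1,
#' one-vs-one) is trained on class-balanced decoding-set samples of the
#' training session and tested on the aligned decoding-set samples of the
#' test session; the reported accuracy is the mean per-class accuracy
#' averaged over `n_rep` Monte-Carlo resamplings of the balanced training
#' set. `aligned = FALSE` skips the transform (control).
#'
#' @param train,test Lists with elements `embedding` (`cd_embedding`) and
#'   `labels` (snippet factor).
#' @param split One element of [class_splits()].
#' @param seed Integer seed.
#' @param aligned Apply the Procrustes transform (default TRUE).
#' @param dims Shared dimensionality (default 4).
#' @param n_rep Monte-Carlo repetitions (default 20).
#' @param max_per_class Cap on balanced training samples per class.
#' @return Decoding report with `accuracy_pct` (mean over repetitions),
#'   `recalls_pct`, `transform`, `audit`; or `NULL` (with a message) if a
#'   decoding class is absent from either session.
#' @export
cross_session_decode <- function(train, test, split, seed = 1L,
                                 aligned = TRUE, dims = 4L, n_rep = 20L,
                                 max_per_class = 200L) {
  xs <- .norm01(train$embedding$coords[, seq_len(dims), drop = FALSE])
  xt <- .norm01(test$embedding$coords[, seq_len(dims), drop = FALSE])
  ls <- .point_labels(train$embedding, train$labels)
  lt <- .point_labels(test$embedding, test$labels)
  dec <- split$decoding
  if (!all(dec %in% ls) || !all(dec %in% lt)) {
    message("decoding class absent from a session; split skipped")
    return(NULL)
  }
  ali_s <- which(ls %in% split$alignment)
  ali_t <- which(lt %in% split$alignment)
  dec_s <- which(ls %in% dec)
  dec_t <- which(lt %in% dec)
  if (aligned) {
    ms <- do.call(rbind, lapply(split$alignment, function(cl)
      colMeans(xs[ls == cl, , drop = FALSE])))
    mt <- do.call(rbind, lapply(split$alignment, function(cl)
      colMeans(xt[lt == cl, , drop = FALSE])))
    rownames(ms) <- rownames(mt) <- split$alignment
    tf <- procrustes_align(ms, mt)
    xt_use <- apply_alignment(tf, xt)
  } else {
    tf <- NULL
    xt_use <- xt
  }
  ytr <- factor(as.character(ls[dec_s]), levels = dec)
  yte <- factor(as.character(lt[dec_t]), levels = dec)
  xtr <- xs[dec_s, , drop = FALSE]
  xte <- xt_use[dec_t, , drop = FALSE]
  n_bal <- min(min(table(ytr)), max_per_class)
  accs <- numeric(n_rep)
  rec <- matrix(0, n_rep, length(dec), dimnames = list(NULL, dec))
  with_seed(seed, {
    for (r in seq_len(n_rep)) {
      take <- unlist(lapply(dec, function(cl) {
        ix <- which(ytr == cl)
        ix[sample.int(length(ix), n_bal)]
      }))
      fit <- e1071::svm(xtr[take, , drop = FALSE], droplevels(ytr[take]),
                        kernel = "radial", gamma = 1, cost = 1, scale = FALSE)
      pred <- stats::predict(fit, xte)
      accs[r] <- 100 * mean_per_class_accuracy(pred, yte)
      for (cl in dec) rec[r, cl] <- 100 * mean(pred[yte == cl] == cl)
    }
  })
  list(accuracy_pct = mean(accs), recalls_pct = colMeans(rec),
       rep_accuracies_pct = accs, n_runs = n_rep, aligned = aligned,
       transform = tf,
       audit = list(alignment_train = ali_s, alignment_test = ali_t,
                    decoding_train = dec_s, decoding_test = dec_t,
                    disjoint = length(intersect(ali_s, dec_s)) == 0L &&
                      length(intersect(ali_t, dec_t)) == 0L))
}

#' Generalization matrix over all ordered session pairs
#'
#' Runs [cross_session_decode()] for every ordered (train, test) session
#' pair, including the diagonal, averaging over the supplied class splits.
#' The generalization accuracy of a session is the mean of its row; both
#' the variant including the diagonal and the off-diagonal-only variant
#' are reported.
#'
#' @param sessions Named list of lists with `embedding` and `labels`.
#' @param splits List of class splits (default all 15 with 4 alignment
#'   classes).
#' @param seed Integer seed.
#' @param ... Passed to [cross_session_decode()].
#' @return List: `matrix` (train x test mean accuracies, %),
#'   `generalization_incl_diag`, `generalization_off_diag`.
#' @export
generalization_matrix <- function(sessions, splits = class_splits(4L),
                                  seed = 1L, ...) {
  if (length(sessions) < 2L) stop("need at least 2 sessions")
  ids <- names(sessions) %||% paste0("ses", seq_along(sessions))
  n <- length(sessions)
  M <- matrix(NA_real_, n, n, dimnames = list(train = ids, test = ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    vals <- vapply(seq_along(splits), function(sp) {
      r <- cross_session_decode(sessions[[i]], sessions[[j]], splits[[sp]],
                                seed = seed + 1000L * i + 31L * j + sp, ...)
      if (is.null(r)) NA_real_ else r$accuracy_pct
    }, numeric(1))
    M[i, j] <- mean(vals, na.rm = TRUE)
  }
  off <- M; diag(off) <- NA
  list(matrix = M,
       generalization_incl_diag = rowMeans(M, na.rm = TRUE),
       generalization_off_diag = rowMeans(off, na.rm = TRUE))
}

#' Unit-removal and area-removal ablations of the generalization task
#'
#' Re-embeds every session after removing units and reruns the
#' cross-session decoding. `remove_k_units` removes `k` random units per
#' session (embedding dimension 20 for k up to 40, 10 beyond, following
#' the reduced population sizes); `remove_area` removes all units of one
#' area plus, for a fair comparison, random units from the other areas so
#' that every condition removes `max(#M2, #M1, #S1)` units (dimension 10).
#'
#' @param sessions Named list of lists with `session` (`cd_session`) and
#'   `labels`.
#' @param mode `"remove_k_units"` or `"remove_area"`.
#' @param params For `remove_k_units`: `k_removed` (default
#'   `c(0, 20, 40, 60, 80)`). For `remove_area`: `areas` (default all
#'   three).
#' @param seed Integer seed.
#' @param min_active Activity filter passed to [preprocess_population()].
#' @param splits,... Passed to [generalization_matrix()].
#' @return Data frame: condition, mean off-diagonal generalization
#'   accuracy (%), n_units_removed, embedding dimension.
#' @export
ablation_harness <- function(sessions, mode = c("remove_k_units", "remove_area"),
                             params = list(), seed = 1L, min_active = 15L,
                             splits = class_splits(4L), ...) {
  mode <- match.arg(mode)
  run_cond <- function(cond_name, drop_fun, d) {
    embs <- lapply(seq_along(sessions), function(i) {
      ses <- sessions[[i]]$session
      keep <- drop_fun(ses, seed + i)
      if (length(keep) <= d) return(NULL)
      sub <- ses
      sub$units <- ses$units[keep, , drop = FALSE]
      sub$spike_times <- ses$spike_times[keep]
      bpm <- preprocess_population(sub, min_active = min_active)
      list(embedding = lem_pipeline(bpm, d = d),
           labels = sessions[[i]]$labels)
    })
    if (any(vapply(embs, is.null, logical(1)))) {
      message("condition ", cond_name, " skipped: too few units remain")
      return(NA_real_)
    }
    names(embs) <- names(sessions)
    gm <- generalization_matrix(embs, splits = splits, seed = seed, ...)
    mean(gm$generalization_off_diag, na.rm = TRUE)
  }
  if (mode == "remove_k_units") {
    ks <- params$k_removed %||% c(0L, 20L, 40L, 60L, 80L)
    res <- lapply(ks, function(k) {
      d <- if (k <= 40L) 20L else 10L
      d <- min(d, min(vapply(sessions, function(s) nrow(s$session$units),
                             integer(1))) - k - 1L)
      if (d < 3L) return(data.frame(condition = paste0("remove_", k),
                                    accuracy_pct = NA_real_,
                                    n_removed = k, d = NA_integer_))
      acc <- run_cond(paste0("remove_", k), function(ses, sd) {
        n <- nrow(ses$units)
        if (k == 0L) seq_len(n)
        else with_seed(sd, sort(sample.int(n, n - k)))
      }, d)
      data.frame(condition = paste0("remove_", k), accuracy_pct = acc,
                 n_removed = k, d = d)
    })
  } else {
    areas <- params$areas %||% AREAS
    res <- lapply(areas, function(ar) {
      acc <- run_cond(paste0("remove_", ar), function(ses, sd) {
        cnt <- table(factor(ses$units$area, AREAS))
        n_max <- max(cnt)
        out <- which(ses$units$area == ar)
        extra <- n_max - length(out)
        if (extra > 0L) {
          pool <- setdiff(seq_len(nrow(ses$units)), out)
          out <- c(out, with_seed(sd, sample(pool, extra)))
        }
        setdiff(seq_len(nrow(ses$units)), out)
      }, 10L)
      data.frame(condition = paste0("remove_", ar), accuracy_pct = acc,
                 n_removed = NA_integer_, d = 10L)
    })
  }
  do.call(rbind, res)
}
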