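#' Class-mean population vectors (polytope vertices)
#'
#' Averages population coordinates over the time points labeled with each
#' behavior class. A 100 ms bin inherits the label of its 500 ms snippet.
#'
#' @param x A `cd_embedding` (class means in the embedded space) or a
#'   `cd_binmat` (class means in recording space, one entry per unit).
#' @param labels Snippet-level label factor for the session.
#' @param classes Classes to include (default all six).
#' @return A `cd_class_means`: `means` (classes x dimensions), `counts`
#'   (labeled time points per class), `space` tag.
#' @export
class_means <- function(x, labels, classes = CLASSES) {
  if (inherits(x, "cd_embedding")) {
    coords <- x$coords
    idx <- x$kept_time_index
    space <- paste0(x$method, "-", ncol(coords))
  } else if (inherits(x, "cd_binmat")) {
    coords <- t(x$matrix)
    idx <- x$kept_time_index
    space <- "recording"
  } else stop("x must be a cd_embedding or cd_binmat")
  snip <- (idx - 1L) %/% 5L + 1L
  if (max(snip) > length(labels)) stop("label track shorter than recording")
  lab <- as.character(labels)[snip]
  means <- matrix(NA_real_, length(classes), ncol(coords),
                  dimnames = list(classes, NULL))
  counts <- integer(length(classes)); names(counts) <- classes
  for (cl in classes) {
    sel <- which(lab == cl)
    counts[cl] <- length(sel)
    if (length(sel) == 0L)
      stop("no kept, labeled time points for class: ", cl)
    means[cl, ] <- colMeans(coords[sel, , drop = FALSE])
  }
  structure(list(means = means, counts = counts, space = space),
            class = "cd_class_means")
}

# closed-form least-squares Procrustes (translation, scale, orthogonal
# matrix incl. reflection) mapping Y onto X; matches vegan::procrustes
# with symmetric = FALSE (verified by test).
.procrustes_fit <- function(X, Y) {
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)
  s <- svd(crossprod(Xc, Yc))
  A <- s$v %*% t(s$u)
  scale <- sum(s$d) / sum(Yc^2)
  trans <- xm - scale * as.vector(ym %*% A)
  list(rotation = A, scale = scale, translation = trans,
       Yhat = sweep(scale * Y %*% A, 2, trans, `+`))
}

#' Euclidean distance matrix between class means
#'
#' @param cm A `cd_class_means` (or a plain classes x dims matrix).
#' @return Symmetric class x class distance matrix.
#' @export
class_distance_matrix <- function(cm) {
  m <- if (inherits(cm, "cd_class_means")) cm$means else as.matrix(cm)
  as.matrix(stats::dist(m))
}

#' Jeffries-Matusita distance between two class-distance matrices
#'
#' `d_JM = sqrt( sum_ij ( sqrt(D^v_ij) - sqrt(D^w_ij) )^2 )`, the sum
#' running over all ordered class pairs (the diagonal contributes zero).
#' The square-root transform damps the influence of outlying distances.
#'
#' @param Dv,Dw Symmetric class x class distance matrices.
#' @return Scalar distance.
#' @export
jm_distance <- function(Dv, Dw) {
  stopifnot(all(dim(Dv) == dim(Dw)))
  sqrt(sum((sqrt(Dv) - sqrt(Dw))^2))
}

#' Rank concordance of class-distance structure between two sessions
#'
#' For each class i, the remaining classes are ranked by their distance
#' from i in each session (ties broken by the canonical class order);
#' `s_i` counts the classes occupying the same rank in both sessions
#' (maximum `n_classes - 1`, perfect match; minimum 0).
#'
#' @param Dv,Dw Class x class distance matrices with identical
#'   row/column names in identical order.
#' @return Named integer vector `s` with one entry per class.
#' @export
rank_concordance <- function(Dv, Dw) {
  if (any(is.na(Dv)) || any(is.na(Dw))) stop("NaN distances")
  stopifnot(identical(dimnames(Dv), dimnames(Dw)))
  cls <- rownames(Dv)
  k <- length(cls)
  s <- integer(k); names(s) <- cls
  for (i in seq_len(k)) {
    others <- setdiff(seq_len(k), i)
    rv <- order(Dv[i, others], others)   # positions sorted by distance
    rw <- order(Dw[i, others], others)
    # rank of class j = its position in the sorted order
    pos_v <- match(seq_along(others), rv)
    pos_w <- match(seq_along(others), rw)
    s[i] <- sum(pos_v == pos_w)
  }
  s
}

#' Exhaustive null distribution of the rank-concordance statistic
#'
#' Enumerates all permutations of the `n_classes - 1` non-reference ranks
#' (120 for six classes) and forms all unordered pairs of permutations
#' including self-pairs (7260 for six classes); each pair contributes the
#' number of positions at which the two permutations agree. Supplies the
#' reference distribution for a two-sample Kolmogorov-Smirnov comparison
#' with observed `s` values.
#'
#' @param n_classes 5 or 6.
#' @return List: `s_boot` (null statistic values, one per unordered pair),
#'   `n_perms`, `n_pairs`.
#' @export
rank_null_distribution <- function(n_classes = 6L) {
  stopifnot(n_classes %in% c(5L, 6L))
  k <- n_classes - 1L
  P <- perm_matrix(k)
  np <- nrow(P)
  M <- matrix(0L, np, np)
  for (pos in seq_len(k))
    M <- M + outer(P[, pos], P[, pos], `==`)
  s_boot <- M[upper.tri(M, diag = TRUE)]
  list(s_boot = as.integer(s_boot), n_perms = np,
       n_pairs = np * (np + 1L) / 2L)
}

#' Kolmogorov-Smirnov comparison of observed rank concordance with its null
#'
#' @param s_observed Integer vector of observed `s` statistics (pooled over
#'   session pairs and classes).
#' @param n_classes Number of classes the statistics were computed on.
#' @return The `htest` object of the two-sample, two-sided KS test.
#' @export
rank_ks_test <- function(s_observed, n_classes = 6L) {
  null <- rank_null_distribution(n_classes)
  suppressWarnings(stats::ks.test(s_observed, null$s_boot))
}

#' Polytope similarity test (Jeffries-Matusita with exhaustive label null)
#'
#' Procrustes-rescales session w's class means onto session v's, computes
#' the two class-distance matrices and their Jeffries-Matusita distance,
#' and compares the observed value with the exhaustive null obtained by
#' recomputing it under every permutation of w's class labels (720 for six
#' classes; the identity permutation is included, so the smallest
#' attainable one-sided p-value is 1/720).
#'
#' @param cm_v,cm_w `cd_class_means` objects in spaces of equal dimension.
#' @param exclude_rest Drop the "rest" class before testing (null then has
#'   5! = 120 permutations).
#' @return A `cd_polytope_comparison`: `s` (rank concordance per class),
#'   `d_jm`, `p_value`, `n_perm`, `null` (all null values), `options`.
#' @export
jm_similarity_test <- function(cm_v, cm_w, exclude_rest = FALSE) {
  V <- if (inherits(cm_v, "cd_class_means")) cm_v$means else as.matrix(cm_v)
  W <- if (inherits(cm_w, "cd_class_means")) cm_w$means else as.matrix(cm_w)
  stopifnot(identical(rownames(V), rownames(W)))
  if (exclude_rest) {
    keep <- setdiff(rownames(V), "rest")
    V <- V[keep, , drop = FALSE]; W <- W[keep, , drop = FALSE]
  }
  k <- nrow(V)
  if (k < 3L) stop("Procrustes underdetermined with fewer than 3 classes")
  if (ncol(V) != ncol(W)) stop("class-mean spaces have different dimensions")
  Dv <- as.matrix(stats::dist(V))
  perms <- perm_matrix(k)
  null <- numeric(nrow(perms))
  for (p in seq_len(nrow(perms))) {
    Wp <- W[perms[p, ], , drop = FALSE]
    fit <- .procrustes_fit(V, Wp)
    Dw <- as.matrix(stats::dist(fit$Yhat))
    null[p] <- sqrt(sum((sqrt(Dv) - sqrt(Dw))^2))
  }
  obs <- null[1L]  # identity permutation is lexicographically first
  s <- rank_concordance(Dv, structure(as.matrix(stats::dist(W)),
                                      dimnames = dimnames(Dv)))
  structure(list(s = s, d_jm = obs, p_value = mean(null <= obs),
                 n_perm = nrow(perms), null = null,
                 options = list(exclude_rest = exclude_rest,
                                space = c(if (inherits(cm_v, "cd_class_means"))
                                  cm_v$space else "matrix"))),
            class = "cd_polytope_comparison")
}

#' Somatotopy-shuffle control for the polytope similarity test
#'
#' Repeats the Jeffries-Matusita similarity test after destroying
#' single-unit identity within somatotopic regions: for every permutation,
#' each session's class-mean population vectors are rebuilt with the unit
#' entries shuffled within their somatotopic region, independently for
#' every class. This preserves each region's per-class mean activity (and
#' hence any region-level covariance structure) while removing unit-level
#' coding. Reports the average p-value across permutations.
#'
#' @param cm_v,cm_w Recording-space `cd_class_means` (classes x units).
#' @param regions_v,regions_w Somatotopic region label per unit of each
#'   session.
#' @param n_perm Number of shuffles (default 500).
#' @param seed Integer seed.
#' @param exclude_rest Passed to [jm_similarity_test()].
#' @param alpha Level for the pass/fail summary.
#' @return List: `mean_p`, `significant` (`mean_p < alpha`), `p_values`.
#' @export
somatotopy_shuffle_test <- function(cm_v, cm_w, regions_v, regions_w,
                                    n_perm = 500L, seed = 1L,
                                    exclude_rest = FALSE, alpha = 0.05) {
  V <- cm_v$means; W <- cm_w$means
  if (anyNA(regions_v) || anyNA(regions_w) ||
      any(regions_v == "unknown") || any(regions_w == "unknown"))
    stop("somatotopic region labels required for all units")
  stopifnot(length(regions_v) == ncol(V), length(regions_w) == ncol(W))
  for (r in unique(c(regions_v, regions_w)))
    if (sum(regions_v == r) == 1L || sum(regions_w == r) == 1L)
      message("region '", r, "' has a single unit; shuffle is the identity there")
  shuffle_cm <- function(M, regions) {
    out <- M
    for (r in unique(regions)) {
      ix <- which(regions == r)
      if (length(ix) > 1L)
        for (cl in seq_len(nrow(M)))
          out[cl, ix] <- M[cl, ix[sample.int(length(ix))]]
    }
    out
  }
  p_values <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    jm_similarity_test(shuffle_cm(V, regions_v), shuffle_cm(W, regions_w),
                       exclude_rest = exclude_rest)$p_value
  }, numeric(1)))
  list(mean_p = mean(p_values), significant = mean(p_values) < alpha,
       p_values = p_values)
}
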