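#' Binarized population matrix at 100 ms resolution
#'
#' Bins a session's spikes (single and multi units alike) in 100 ms bins,
#' binarizes (1 for at least one spike), and keeps only time points with at
#' least `min_active` active units. Sessions with fewer than 5000 kept time
#' points are flagged (`full_scale = FALSE`) rather than rejected, so that
#' reduced problem sizes remain usable.
#'
#' @param session A `cd_session`.
#' @param min_active Minimum number of active units per kept time point.
#' @param bin_s Bin width (default 0.1 s).
#' @return A `cd_binmat`: `matrix` (units x kept time points, 0/1),
#'   `kept_time_index` (original 100 ms bin per column), `min_active`,
#'   `bin_s`, `full_scale`.
#' @export
preprocess_population <- function(session, min_active = 15L, bin_s = 0.1) {
  if (nrow(session$units) < 1L) stop("session has no units")
  counts <- bin_spikes(session, bin_s)
  b <- (counts >= 1L) * 1L
  kept <- which(colSums(b) >= min_active)
  structure(list(matrix = b[, kept, drop = FALSE],
                 kept_time_index = kept,
                 min_active = as.integer(min_active), bin_s = bin_s,
                 full_scale = length(kept) >= 5000L),
            class = "cd_binmat")
}

# k nearest neighbors (excluding self) of every row of `pts`. Distance ties
# (ubiquitous for binary data under the Hamming metric) are broken by a
# fixed multiplicative-hash ordering of the indices: deterministic and
# platform-independent, but free of the systematic temporal bias that
# breaking ties by ascending index would inject into the graph.
# Blocked to bound memory.
.knn_index <- function(pts, k, metric, block = 1024L) {
  t_n <- nrow(pts)
  if (k >= t_n) stop("k (", k, ") must be smaller than the number of points")
  tie_key <- ((seq_len(t_n) * 2654435761) %% 1000003) * t_n + seq_len(t_n)
  if (metric == "hamming") {
    a <- rowSums(pts)
    f <- ncol(pts)
  } else {
    q2 <- rowSums(pts^2)
  }
  nbr <- matrix(0L, t_n, k)
  for (start in seq(1L, t_n, by = block)) {
    ix <- start:min(start + block - 1L, t_n)
    cross <- tcrossprod(pts[ix, , drop = FALSE], pts)  # |ix| x t_n
    d <- if (metric == "hamming") {
      (outer(a[ix], a, `+`) - 2 * cross) / f
    } else {
      outer(q2[ix], q2, `+`) - 2 * cross
    }
    for (j in seq_along(ix)) {
      row <- d[j, ]
      row[ix[j]] <- Inf  # exclude self
      nbr[ix[j], ] <- order(row, tie_key)[seq_len(k)]
    }
  }
  nbr
}

#' Unweighted mutual k-nearest-neighbor graph
#'
#' Points `i` and `j` are connected iff each is among the other's `k`
#' nearest neighbors; distance ties are broken by ascending index and the
#' self-distance is excluded. `k = max(1, round(k_fraction * n))`, with
#' round-half-away-from-zero.
#'
#' @param points Matrix with one point per row. For `metric = "hamming"`
#'   rows are binary vectors and the distance is the mismatch fraction; for
#'   `"euclidean"`, ordinary Euclidean distance.
#' @param k_fraction Neighborhood size as a fraction of the number of
#'   points (ignored when `k` is given).
#' @param metric `"hamming"` or `"euclidean"`.
#' @param k Absolute neighborhood size (optional).
#' @return A `cd_graph`: sparse symmetric 0/1 adjacency `W` (zero
#'   diagonal), `degree`, `k`, `metric`. The unnormalized Laplacian is
#'   `L = D - W`.
#' @export
mutual_knn_graph <- function(points, k_fraction = 0.005,
                             metric = c("hamming", "euclidean"), k = NULL) {
  metric <- match.arg(metric)
  points <- as.matrix(points)
  t_n <- nrow(points)
  if (is.null(k)) k <- max(1L, as.integer(round_half_away(k_fraction * t_n)))
  nbr <- .knn_index(points, k, metric)
  A <- Matrix::sparseMatrix(i = rep(seq_len(t_n), each = k),
                            j = as.integer(t(nbr)), x = 1,
                            dims = c(t_n, t_n))
  W <- A * Matrix::t(A)   # mutual: both directions present
  W@x[] <- 1
  structure(list(W = W, degree = Matrix::rowSums(W), k = k, metric = metric),
            class = "cd_graph")
}

#' Spectral embedding from the random-walk graph Laplacian
#'
#' Solves the generalized eigenvalue problem `L v = lambda D v`
#' (equivalently, eigenvectors of the random-walk normalized Laplacian
#' `D^-1 L`) restricted to the graph's largest connected component, via the
#' symmetric similarity transform `D^-1/2 W D^-1/2` for solver stability.
#' The smallest eigenvalue is zero with a constant eigenvector, which is
#' discarded; the remaining `d` eigenvectors, ordered by ascending
#' eigenvalue, form the embedding. Each eigenvector is scaled to unit norm
#' and its sign fixed so that its largest-magnitude entry is positive.
#'
#' @param graph A `cd_graph`.
#' @param d Number of embedding dimensions (after dropping the constant
#'   eigenvector).
#' @param kept_time_index Optional index vector mapping graph vertices to
#'   original time bins, threaded through the component restriction.
#' @param dense_limit Components up to this size use a dense symmetric
#'   eigendecomposition; larger ones use ARPACK.
#' @return A `cd_embedding`: `coords` (points x d), `eigenvalues`
#'   (ascending, constant mode removed), `method = "LEM"`,
#'   `kept_time_index`, `params` (includes the fraction of points dropped
#'   with the component restriction).
#' @export
spectral_embed <- function(graph, d, kept_time_index = NULL,
                           dense_limit = 400L) {
  W <- graph$W
  n <- nrow(W)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected")
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  dropped <- 1 - length(keep) / n
  if (dropped > 0.2)
    warning(sprintf("component restriction dropped %.1f%% of points",
                    100 * dropped))
  W <- W[keep, keep, drop = FALSE]
  deg <- Matrix::rowSums(W)
  if (any(deg == 0)) stop("isolated vertices after component restriction")
  m <- length(keep)
  if (d + 1L > m) stop("more dimensions requested than points available")
  ds <- 1 / sqrt(deg)
  Ws <- Matrix::Diagonal(x = ds) %*% W %*% Matrix::Diagonal(x = ds)
  if (m <= dense_limit) {
    e <- eigen(as.matrix(Ws), symmetric = TRUE)
    mu <- e$values[seq_len(d + 1L)]
    U <- e$vectors[, seq_len(d + 1L), drop = FALSE]
  } else {
    # fixed RNG state for the ARPACK starting vector: identical graphs give
    # bit-identical eigenvectors
    ar <- with_seed(1L,
      igraph::arpack(function(x, extra) as.vector(Ws %*% x), sym = TRUE,
                     options = list(n = m, nev = d + 1L,
                                    ncv = min(m, max(4L * (d + 1L), 60L)),
                                    which = "LA", maxiter = 5000L)))
    ord <- order(ar$values, decreasing = TRUE)
    mu <- ar$values[ord]
    U <- ar$vectors[, ord, drop = FALSE]
  }
  lambda <- 1 - mu                     # ascending; first ~ 0 (constant mode)
  V <- U * ds                          # back-transform to random-walk vectors
  V <- sweep(V, 2, sqrt(colSums(V^2)), `/`)
  # deterministic sign: largest-|entry| positive
  for (j in seq_len(ncol(V))) {
    i0 <- which.max(abs(V[, j]))
    if (V[i0, j] < 0) V[, j] <- -V[, j]
  }
  coords <- V[, -1L, drop = FALSE]
  structure(list(
    coords = coords, eigenvalues = lambda[-1L], method = "LEM",
    kept_time_index = if (!is.null(kept_time_index)) kept_time_index[keep]
    else keep,
    params = list(k = graph$k, metric = graph$metric,
                  dropped_fraction = dropped, zero_eigenvalue = lambda[1L])
  ), class = "cd_embedding")
}

#' Two-iteration Laplacian-eigenmap pipeline
#'
#' Iteration 1 builds a mutual kNN graph on the binarized population
#' vectors with the Hamming distance and 0.5% of the time points as
#' neighbors and embeds to `d` dimensions; iteration 2 rebuilds the graph
#' on the iteration-1 coordinates with the Euclidean distance and 7.5%
#' neighbors and embeds again. The kept-time-point index is threaded
#' through both component restrictions.
#'
#' @param bpm A `cd_binmat` from [preprocess_population()].
#' @param d Embedding dimension (default 20).
#' @param k1_fraction,k2_fraction Neighbor fractions of the two iterations.
#' @param metric2 Metric of the second iteration (default `"euclidean"`).
#' @return Final `cd_embedding` (see [spectral_embed()]); `params` records
#'   both iterations.
#' @export
lem_pipeline <- function(bpm, d = 20L, k1_fraction = 0.005,
                         k2_fraction = 0.075, metric2 = "euclidean") {
  stopifnot(inherits(bpm, "cd_binmat"))
  if (!bpm$full_scale)
    message("session below the 5000 kept-time-point floor; ",
            "proceeding at reduced scale")
  g1 <- mutual_knn_graph(t(bpm$matrix), k_fraction = k1_fraction,
                         metric = "hamming")
  e1 <- spectral_embed(g1, d, kept_time_index = bpm$kept_time_index)
  g2 <- mutual_knn_graph(e1$coords, k_fraction = k2_fraction, metric = metric2)
  e2 <- spectral_embed(g2, d, kept_time_index = e1$kept_time_index)
  e2$params <- list(iteration1 = e1$params, iteration2 = e2$params,
                    d = d, k1_fraction = k1_fraction,
                    k2_fraction = k2_fraction, metric2 = metric2)
  e2
}

#' Shuffle and shift control transforms for a population matrix
#'
#' `time_shuffle` permutes time points (columns) globally, preserving every
#' population vector; `neuron_shuffle` permutes each unit's (row's) entries
#' independently, preserving row sums but destroying co-activity;
#' `time_shift` rotates each row circularly by an independent random
#' offset, preserving every unit's autocorrelation.
#'
#' @param mat Units x time matrix (binary or counts).
#' @param mode One of `"time_shuffle"`, `"neuron_shuffle"`, `"time_shift"`.
#' @param seed Integer seed.
#' @return Transformed matrix of identical dimensions.
#' @export
control_transforms <- function(mat,
                               mode = c("time_shuffle", "neuron_shuffle",
                                        "time_shift"),
                               seed = 1L) {
  mode <- match.arg(mode)
  t_n <- ncol(mat)
  with_seed(seed, switch(mode,
    time_shuffle = mat[, sample.int(t_n), drop = FALSE],
    neuron_shuffle = {
      out <- mat
      for (i in seq_len(nrow(mat))) out[i, ] <- mat[i, sample.int(t_n)]
      out
    },
    time_shift = {
      out <- mat
      offs <- sample.int(t_n, nrow(mat), replace = TRUE)
      for (i in seq_len(nrow(mat))) {
        s <- offs[i]
        out[i, ] <- mat[i, ((seq_len(t_n) - 1L + s) %% t_n) + 1L]
      }
      out
    }))
}

#' Intrinsic dimensionality from neighborhood growth
#'
#' Computes the average number of neighbors of all points within circles of
#' increasing radius, then the local slope of log(neighbors) against
#' log(radius) (least-squares line over a sliding 5-point window), and
#' returns the slope at the steepest point. For samples from a
#' d-dimensional manifold the neighbor count grows like `r^d` below the
#' manifold's extent, so the steepest log-log slope estimates d. Radii with
#' zero neighbors are excluded. The estimate is invariant to uniform
#' rescaling of the coordinates.
#'
#' @param coords Points x dimensions matrix (>= 500 points recommended).
#' @param n_radii Number of log-spaced radii (default 40).
#' @param max_points Subsample cap for the pairwise distances (seeded,
#'   deterministic).
#' @param seed Seed for the subsample when `nrow(coords) > max_points`.
#' @return Scalar dimensionality estimate.
#' @export
estimate_dimensionality <- function(coords, n_radii = 40L,
                                    max_points = 3000L, seed = 1L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n > max_points) {
    keep <- with_seed(seed, sort(sample.int(n, max_points)))
    coords <- coords[keep, , drop = FALSE]
    n <- max_points
  }
  dv <- as.numeric(stats::dist(coords))
  dv <- sort(dv[dv > 0])
  r <- exp(seq(log(stats::quantile(dv, 0.002)), log(max(dv)),
               length.out = n_radii))
  neigh <- 2 * findInterval(r, dv) / n   # mean neighbors within r
  # restrict to the small-radius growth regime: below ~n/20 mean neighbors
  # the count still scales like r^d; beyond it, closure of the manifold
  # and saturation distort the slope
  ok <- neigh >= 2 & neigh <= n / 20
  if (sum(ok) < 5L) ok <- neigh > 0
  lr <- log(r[ok]); ln <- log(neigh[ok])
  m <- length(lr)
  if (m < 5L) stop("too few usable radii for a slope estimate")
  slopes <- vapply(3:(m - 2L), function(i) {
    w <- (i - 2L):(i + 2L)
    stats::cov(lr[w], ln[w]) / stats::var(lr[w])
  }, numeric(1))
  max(slopes)
}
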