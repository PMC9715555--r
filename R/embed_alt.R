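#' Landmark Isomap embedding of a binarized population matrix
#'
#' Builds a kNN graph (0.5% neighbors, Hamming distance, symmetrized by
#' union, edges weighted by distance), computes geodesic distances from a
#' random subset of landmark points (default 10% of the time points), and
#' embeds all points by landmark multidimensional scaling (Nystrom
#' triangulation from the landmark eigensystem). Disconnected graphs are
#' restricted to their largest component with a warning.
#'
#' @param bpm A `cd_binmat`, or a plain points-in-rows matrix.
#' @param d Embedding dimension.
#' @param k_fraction Neighbor fraction (default 0.005).
#' @param landmark_fraction Fraction of points used as landmarks.
#' @param metric Distance for the neighbor graph.
#' @param seed Seed for the landmark draw.
#' @return A `cd_embedding` with `method = "Isomap"`; `eigenvalues` are the
#'   landmark MDS eigenvalues (descending).
#' @export
isomap_embed <- function(bpm, d = 20L, k_fraction = 0.005,
                         landmark_fraction = 0.1,
                         metric = c("hamming", "euclidean"), seed = 1L) {
  metric <- match.arg(metric)
  if (inherits(bpm, "cd_binmat")) {
    pts <- t(bpm$matrix)
    kept <- bpm$kept_time_index
  } else {
    pts <- as.matrix(bpm)
    kept <- seq_len(nrow(pts))
  }
  t_n <- nrow(pts)
  k <- max(1L, as.integer(round_half_away(k_fraction * t_n)))
  nbr <- .knn_index(pts, k, metric)
  # union-symmetrized weighted kNN graph
  i <- rep(seq_len(t_n), each = k)
  j <- as.integer(t(nbr))
  w <- if (metric == "hamming") {
    vapply(seq_along(i), function(e) mean(pts[i[e], ] != pts[j[e], ]),
           numeric(1))
  } else {
    sqrt(rowSums((pts[i, , drop = FALSE] - pts[j, , drop = FALSE])^2))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = i, to = j, weight = pmax(w, 1e-12)),
    directed = FALSE, vertices = data.frame(name = seq_len(t_n)))
  g <- igraph::simplify(g, edge.attr.comb = "min")
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  if (length(keep) < t_n)
    warning(sprintf("geodesic graph disconnected; kept %d of %d points",
                    length(keep), t_n))
  g <- igraph::induced_subgraph(g, keep)
  m_all <- length(keep)
  n_land <- max(d + 2L, as.integer(ceiling(landmark_fraction * m_all)))
  land <- with_seed(seed, sort(sample.int(m_all, min(n_land, m_all))))
  geo <- igraph::distances(g, v = land)          # landmarks x all points
  if (any(!is.finite(geo))) stop("infinite geodesic distance inside component")
  D2l <- geo[, land, drop = FALSE]^2             # landmark squared distances
  nl <- length(land)
  J <- diag(nl) - 1 / nl
  B <- -0.5 * J %*% D2l %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- which(e$values > 1e-10)[seq_len(min(d, sum(e$values > 1e-10)))]
  lam <- e$values[pos]
  V <- e$vectors[, pos, drop = FALSE]
  # triangulate every point from its squared geodesics to the landmarks
  mu <- rowMeans(D2l)
  X <- 0.5 * t(V / rep(sqrt(lam), each = nl)) %*% (mu - geo)  # d x all
  coords <- t(X)
  for (jj in seq_len(ncol(coords))) {
    i0 <- which.max(abs(coords[, jj]))
    if (coords[i0, jj] < 0) coords[, jj] <- -coords[, jj]
  }
  structure(list(coords = coords, eigenvalues = lam, method = "Isomap",
                 kept_time_index = kept[keep],
                 params = list(k = k, metric = metric,
                               landmark_fraction = landmark_fraction,
                               n_landmarks = nl, seed = seed)),
            class = "cd_embedding")
}

#' PCA embedding of non-binarized population counts
#'
#' Principal component analysis of the 100 ms spike-count matrix (no
#' binarization), restricted to the same time-point filter as the
#' binarized pipeline (at least `min_active` active units).
#'
#' @param session A `cd_session`.
#' @param d Number of components.
#' @param min_active Time-point filter threshold (on the binarized counts).
#' @return A `cd_embedding` with `method = "PCA"`; `eigenvalues` are the
#'   component variances (descending).
#' @export
pca_embed <- function(session, d = 20L, min_active = 15L) {
  counts <- bin_spikes(session, 0.1)
  kept <- which(colSums(counts >= 1L) >= min_active)
  X <- t(counts[, kept, drop = FALSE])
  d <- min(d, ncol(X), nrow(X) - 1L)
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = d)
  coords <- p$x[, seq_len(d), drop = FALSE]
  for (jj in seq_len(ncol(coords))) {
    i0 <- which.max(abs(coords[, jj]))
    if (coords[i0, jj] < 0) coords[, jj] <- -coords[, jj]
  }
  structure(list(coords = coords, eigenvalues = p$sdev[seq_len(d)]^2,
                 method = "PCA", kept_time_index = kept,
                 params = list(min_active = min_active)),
            class = "cd_embedding")
}

#' Area-restricted embedding from a fixed number of sampled units
#'
#' Samples `n_units` units from one sensorimotor area and reruns the full
#' two-iteration Laplacian-eigenmap pipeline on the subset, reduced to
#' `d = 6` dimensions of which 5 remain usable after the constant mode is
#' discarded. Because far fewer units are available, the activity filter is
#' scaled down with the population.
#'
#' @param session A `cd_session`.
#' @param area One of `"M2"`, `"M1"`, `"S1"`.
#' @param n_units Units to sample (default 20); if the area has fewer, the
#'   analysis is skipped with a message and `NULL` is returned.
#' @param d Embedding dimension before discarding the constant mode.
#' @param min_active Activity filter for the subset (default scales the
#'   15-of-a-full-population criterion to the subset size).
#' @param seed Seed for the unit draw.
#' @return A `cd_embedding` with the sampled unit ids in `params`, or
#'   `NULL` if the area is too small.
#' @export
area_subset_embedding <- function(session, area, n_units = 20L, d = 6L,
                                  min_active = max(3L, round(0.2 * n_units)),
                                  seed = 1L) {
  area <- match.arg(area, AREAS)
  in_area <- which(session$units$area == area)
  if (length(in_area) < n_units) {
    message("area ", area, " has ", length(in_area), " < ", n_units,
            " units; skipped")
    return(NULL)
  }
  pick <- with_seed(seed, sort(sample(in_area, n_units)))
  sub <- session
  sub$units <- session$units[pick, , drop = FALSE]
  sub$spike_times <- session$spike_times[pick]
  bpm <- preprocess_population(sub, min_active = min_active)
  # d counts the constant mode: reducing to 6 dimensions leaves 5 usable
  emb <- lem_pipeline(bpm, d = d - 1L)
  emb$params$sampled_units <- session$units$unit_id[pick]
  emb$params$area <- area
  emb
}
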