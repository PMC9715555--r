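#' Single-unit behavioral selectivity (rank-sum with BH correction)
#'
#' Tests, for each behavior class, whether a unit's 500 ms spike counts
#' during the class exceed its counts during the remainder of the session
#' (one-sided Wilcoxon rank-sum), with Benjamini-Hochberg correction across
#' the classes tested for that unit.
#'
#' @param counts Integer vector of spike counts per 500 ms snippet.
#' @param labels Factor of snippet labels (the six behavior classes; other
#'   values such as "unlabeled" are ignored).
#' @param alpha Significance level after correction (default 0.05).
#' @param min_n Minimum samples in the class and in its complement.
#' @return Data frame per class: `class`, `p`, `p_adj`, `selective`
#'   (`NA` where the class is absent or too small).
#' @export
selectivity_test <- function(counts, labels, alpha = 0.05, min_n = 5L) {
  stopifnot(length(counts) == length(labels))
  lab <- as.character(labels)
  p <- rep(NA_real_, length(CLASSES))
  names(p) <- CLASSES
  for (cl in CLASSES) {
    inc <- lab == cl
    other <- lab %in% setdiff(CLASSES, cl)
    if (sum(inc) >= min_n && sum(other) >= min_n) {
      p[cl] <- stats::wilcox.test(counts[inc], counts[other],
                                  alternative = "greater", exact = FALSE)$p.value
    }
  }
  p_adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  p_adj[ok] <- stats::p.adjust(p[ok], method = "BH")
  data.frame(class = CLASSES, p = unname(p), p_adj = p_adj,
             selective = p_adj < alpha)
}

#' Balanced Kruskal-Wallis count of class-pair rate differences
#'
#' Repeatedly subsamples every behavior class to the size of the smallest
#' class, runs a Kruskal-Wallis test on the balanced 500 ms spike counts,
#' and, when the main effect is significant, counts the significant
#' pairwise post-hoc comparisons (two-sided rank-sum at the same level, no
#' multiplicity correction). Returns the average number of significant
#' pairs across resamples, so unequal class frequencies cannot drive the
#' post-hoc significance.
#'
#' @inheritParams selectivity_test
#' @param n_resamples Number of balanced resamples (default 100).
#' @param seed Integer seed for the subsampling.
#' @param alpha Significance level for both the main and post-hoc tests.
#' @return List with `mean_significant_pairs`, `pair_rates` (class x class
#'   matrix of per-pair significance frequencies) and `n_per_class`.
#'   `NA` (with a warning) when the smallest class has fewer than 5
#'   samples.
#' @export
balanced_kruskal_wallis <- function(counts, labels, n_resamples = 100L,
                                    seed = 1L, alpha = 0.05) {
  stopifnot(length(counts) == length(labels))
  lab <- as.character(labels)
  idx_by_class <- lapply(CLASSES, function(cl) which(lab == cl))
  names(idx_by_class) <- CLASSES
  n_min <- min(lengths(idx_by_class))
  if (n_min < 5L) {
    warning("smallest class has fewer than 5 samples; test skipped")
    return(list(mean_significant_pairs = NA_real_, pair_rates = NULL,
                n_per_class = n_min))
  }
  pairs <- utils::combn(CLASSES, 2L)
  pair_hits <- matrix(0, length(CLASSES), length(CLASSES),
                      dimnames = list(CLASSES, CLASSES))
  totals <- numeric(n_resamples)
  with_seed(seed, {
    for (r in seq_len(n_resamples)) {
      take <- lapply(idx_by_class, function(ix) ix[sample.int(length(ix), n_min)])
      x <- unlist(lapply(take, function(ix) counts[ix]), use.names = FALSE)
      g <- factor(rep(CLASSES, each = n_min), levels = CLASSES)
      if (stats::kruskal.test(x, g)$p.value < alpha) {
        for (j in seq_len(ncol(pairs))) {
          a <- counts[take[[pairs[1, j]]]]
          b <- counts[take[[pairs[2, j]]]]
          pv <- stats::wilcox.test(a, b, exact = FALSE)$p.value
          if (!is.na(pv) && pv < alpha) {
            totals[r] <- totals[r] + 1
            pair_hits[pairs[1, j], pairs[2, j]] <-
              pair_hits[pairs[1, j], pairs[2, j]] + 1
          }
        }
      }
    }
  })
  list(mean_significant_pairs = mean(totals),
       pair_rates = (pair_hits + t(pair_hits)) / n_resamples,
       n_per_class = n_min)
}

#' Spike counts on the 500 ms snippet grid
#'
#' @param session A `cd_session`.
#' @return Integer matrix, units x snippets.
#' @export
snippet_counts <- function(session) {
  bin_spikes(session, bin_s = session$snippet_s)
}
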