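#' Binarize a paw velocity trace into swing and stance
#'
#' A 10 ms bin is labeled swing (1) when the horizontal speed strictly
#' exceeds the threshold (default 0.3 mm per 10 ms, i.e. 0.03 mm/ms) and
#' stance (0) otherwise. Boundary values equal to the threshold are stance.
#'
#' @param velocity Numeric vector of horizontal speeds, mm per 10 ms bin.
#' @param threshold Swing threshold in mm per 10 ms (> 0).
#' @param paw Optional paw name, one of `r toString(PAWS)`.
#' @return A `cd_swing_stance` object: integer 0/1 vector with attributes
#'   `paw` and `threshold`.
#' @export
binarize_paw <- function(velocity, threshold = 0.3, paw = NULL) {
  if (!is.null(paw)) paw <- match.arg(paw, PAWS)
  stopifnot(threshold > 0)
  bad <- which(!is.finite(velocity))
  if (length(bad))
    stop("non-finite velocity at index ", bad[1])
  structure(as.integer(velocity > threshold),
            paw = paw, threshold = threshold, class = "cd_swing_stance")
}

#' Swing-stance series for every paw of a session
#'
#' @param session A `cd_session`.
#' @param threshold Swing threshold, mm per 10 ms.
#' @return Integer 0/1 matrix, 10 ms rows x 4 paw columns.
#' @export
swing_stance_matrix <- function(session, threshold = 0.3) {
  out <- matrix(0L, nrow(session$velocity), ncol(session$velocity),
                dimnames = dimnames(session$velocity))
  for (p in colnames(out))
    out[, p] <- as.integer(binarize_paw(session$velocity[, p], threshold, p))
  out
}

#' Step rate and stance fraction of a swing-stance series
#'
#' Steps are counted as stance-to-swing transitions; the step rate is the
#' transition count divided by the series duration.
#'
#' @param series A `cd_swing_stance` (or plain 0/1 vector).
#' @param bin_s Bin width in seconds (default 0.01).
#' @return List with `steps_per_s` and `stance_fraction`.
#' @export
step_statistics <- function(series, bin_s = 0.01) {
  v <- as.integer(series)
  if (!length(v)) stop("empty swing-stance series")
  stopifnot(all(v %in% 0:1))
  n_steps <- sum(v[-1] == 1L & v[-length(v)] == 0L)
  list(steps_per_s = n_steps / (length(v) * bin_s),
       stance_fraction = mean(1 - v))
}

#' Expand a 500 ms label track to the 10 ms grid
#'
#' Each snippet label is repeated 50 times; `unlabeled` propagates.
#'
#' @param labels Factor or character vector of snippet labels.
#' @param n_bins Optional expected length of the output; an error is raised
#'   if it is not exactly 50 times the number of snippets.
#' @return Character (or factor) vector of per-10 ms labels.
#' @export
expand_labels <- function(labels, n_bins = NULL) {
  out <- rep(labels, each = 50L)
  if (!is.null(n_bins) && length(out) != n_bins)
    stop("label track (", length(labels), " snippets -> ", length(out),
         " bins) misaligned with ", n_bins, " velocity bins")
  out
}

#' Contract a per-10 ms label sequence back to the 500 ms grid
#'
#' Majority vote within each block of fifty 10 ms bins; ties broken by the
#' canonical class order. Inverse of [expand_labels()] for constant blocks.
#'
#' @param labels10 Per-10 ms label vector; length must be a multiple of 50.
#' @return Vector of snippet labels.
#' @export
contract_labels <- function(labels10) {
  if (length(labels10) %% 50L != 0L)
    stop("length of 10 ms label sequence is not a multiple of 50")
  lv <- if (is.factor(labels10)) levels(labels10) else
    unique(c(intersect(c(CLASSES, "unlabeled"), unique(as.character(labels10))),
             unique(as.character(labels10))))
  x <- factor(as.character(labels10), levels = lv)
  blocks <- matrix(as.integer(x), nrow = 50L)
  idx <- apply(blocks, 2, function(b) {
    tb <- tabulate(b, nbins = length(lv))
    which.max(tb)  # first max: tie broken by level order
  })
  out <- lv[idx]
  if (is.factor(labels10)) factor(out, levels = lv) else out
}
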