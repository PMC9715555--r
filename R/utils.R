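#' @keywords internal
"_PACKAGE"

# Canonical behavior classes, in the fixed order used for all rank and
# permutation tie-breaking.
CLASSES <- c("step", "turn", "drink", "groom", "rear", "rest")

PAWS <- c("front-left", "front-right", "hind-left", "hind-right")

AREAS <- c("M2", "M1", "S1")

#' Canonical behavior classes
#'
#' The six behavior classes, in the canonical order used throughout the
#' package for rank tie-breaking and label permutation: step, turn, drink,
#' groom, rear, rest.
#'
#' @return Character vector of length six.
#' @export
behavior_classes <- function() CLASSES

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All stochastic operations in the package
# route their seed through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# round-half-away-from-zero (R's round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# All permutations of 1..n as an (n!) x n integer matrix, lexicographic.
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_matrix(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    idx <- row + seq_len(nrow(sub))
    out[idx, 1L] <- first
    out[idx, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    row <- row + nrow(sub)
  }
  out
}

# Normalized Gaussian smoothing along a vector (reflecting edges), sd in bins.
gaussian_smooth <- function(x, sd_bins) {
  if (sd_bins <= 0) return(x)
  half <- max(1L, ceiling(3 * sd_bins))
  kern <- stats::dnorm(seq(-half, half), sd = sd_bins)
  kern <- kern / sum(kern)
  n <- length(x)
  xp <- c(rev(x[seq_len(half)]), x, rev(x[n + 1 - seq_len(half)]))
  out <- stats::filter(xp, kern, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

# Linear cross-correlation via FFT: c[l] = sum_t a[t] * b[t + l] for the
# requested lags (b indexed beyond its support counts as zero).
xcorr_lags <- function(a, b, lags) {
  n <- length(a)
  stopifnot(length(b) == n)
  L <- stats::nextn(n + max(abs(lags)) + 1, 2)
  fa <- stats::fft(c(a, numeric(L - n)))
  fb <- stats::fft(c(b, numeric(L - n)))
  cc <- Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / L
  # lag l >= 0 at position l+1; lag l < 0 wraps to position L+l+1
  pos <- ifelse(lags >= 0, lags + 1, L + lags + 1)
  cc[pos]
}

# Circular cross-correlation over all lags 0..n-1: C[l+1] = sum_t a[t]*b[(t+l-1) %% n + 1]
circular_xcorr <- function(a, b) {
  n <- length(a)
  stopifnot(length(b) == n)
  Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
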