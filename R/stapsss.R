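#' Spike-triggered average paw swing-stance status (STAPSSS)
#'
#' Averages a paw's binary swing-stance trace in windows of +/- 1 s (201
#' bins of 10 ms) around every spike of a unit; bins holding k spikes
#' contribute k windows. Windows clipped at the recording edges are
#' excluded. The waveform is normalized by its mean, so a unit whose firing
#' carries no information about the paw has a flat waveform near 1.
#'
#' @param spike_bins Integer vector of 10 ms spike counts.
#' @param status Binary swing-stance vector on the same 10 ms grid
#'   (see [binarize_paw()]).
#' @return List with `waveform` (201 mean-normalized values, lag -1000 ms to
#'   +1000 ms), `waveform_std`, `n_spikes` (spikes with full windows).
#' @export
compute_stapsss <- function(spike_bins, status) {
  status <- as.numeric(status)
  spike_bins <- as.numeric(spike_bins)
  n <- length(status)
  if (length(spike_bins) != n)
    stop("spike_bins and status must share length")
  if (n < 201) stop("recording shorter than the +/- 1 s window")
  interior <- spike_bins
  interior[c(seq_len(100L), (n - 99L):n)] <- 0
  n_sp <- sum(interior)
  if (n_sp == 0) stop("zero usable spikes (after edge-window exclusion)")
  raw <- xcorr_lags(interior, status, -100:100) / n_sp
  m <- mean(raw)
  w <- if (m > 0) raw / m else raw
  list(waveform = w, waveform_std = stats::sd(w), n_spikes = n_sp)
}

#' Shift-bootstrap control quantile for STAPSSS
#'
#' Circularly rotates the spike train by uniform random offsets at least
#' 1 s away from zero, recomputes the (mean-normalized) STAPSSS waveform
#' standard deviation for each rotation, and returns the empirical 0.99
#' quantile (type-7 convention). Rotation preserves both marginals and the
#' autocorrelation of the series exactly, so autocorrelated paw movement
#' alone cannot produce spurious coupling. For rotated surrogates the series
#' is treated as circular (windows wrap at the recording edge), which makes
#' every surrogate waveform a slice of one precomputed circular
#' cross-correlation.
#'
#' @inheritParams compute_stapsss
#' @param n_shifts Number of random rotations (>= 100; default 1000).
#' @param seed Integer seed for the rotation offsets.
#' @param probs Quantile of the control distribution (default 0.99).
#' @return List with `control_q99_std`, the vector `null_stds`, and the
#'   offsets used.
#' @export
shift_null <- function(spike_bins, status, n_shifts = 1000L, seed = 1L,
                       probs = 0.99) {
  status <- as.numeric(status)
  spike_bins <- as.numeric(spike_bins)
  n <- length(status)
  if (length(spike_bins) != n) stop("spike_bins and status must share length")
  if (n < 400) stop("recording shorter than 4 s")
  if (n_shifts < 100) stop("n_shifts must be >= 100")
  n_sp <- sum(spike_bins)
  if (n_sp == 0) stop("zero spikes")
  cc <- circular_xcorr(spike_bins, status)  # cc[l+1] = sum sp[t] st[t+l]
  shifts <- with_seed(seed, sample.int(n - 200L, n_shifts, replace = TRUE) + 99L)
  lagmat <- outer(-100:100, shifts, `+`)          # 201 x n_shifts
  w <- matrix(cc[(lagmat %% n) + 1L], 201L, n_shifts) / n_sp
  mu <- colMeans(w)
  sds <- sqrt(colSums(sweep(w, 2, mu, `-`)^2) / 200)
  ok <- mu > 0
  sds[ok] <- sds[ok] / mu[ok]
  list(control_q99_std = stats::quantile(sds, probs, names = FALSE, type = 7),
       null_stds = sds, shifts = shifts)
}

#' Peak offset of a STAPSSS waveform
#'
#' Offset in ms between the movement peak (largest deviation of the
#' mean-normalized waveform from 1) and the spike at lag 0. Negative values
#' mean the movement peak precedes the spike. Ties are broken toward 0 lag.
#'
#' @param waveform Mean-normalized 201-bin STAPSSS waveform.
#' @return Signed offset in ms, or `NA` for a flat waveform.
#' @export
peak_offset <- function(waveform) {
  stopifnot(length(waveform) == 201L)
  dev <- abs(waveform - 1)
  mx <- max(dev)
  if (mx < 1e-12) return(NA_real_)
  cand <- which(dev >= mx - 1e-12)
  i <- cand[which.min(abs(cand - 101L))]
  10 * (i - 101L)
}

#' STAPSSS coupling of one unit to one paw
#'
#' Combines [compute_stapsss()] and [shift_null()] into the coupling ratio
#' `c = waveform_std / control_q99_std` (significant when `c > 1`) and the
#' peak offset of significant units.
#'
#' @inheritParams shift_null
#' @return List of class `cd_stapsss`: `waveform`, `waveform_std`,
#'   `control_q99_std`, `coupling`, `significant`, `peak_offset`,
#'   `n_spikes`.
#' @export
stapsss_unit <- function(spike_bins, status, n_shifts = 1000L, seed = 1L) {
  obs <- compute_stapsss(spike_bins, status)
  ctl <- shift_null(spike_bins, status, n_shifts = n_shifts, seed = seed)
  coup <- if (ctl$control_q99_std > 0) obs$waveform_std / ctl$control_q99_std
  else if (obs$waveform_std > 0) Inf else 0
  sig <- is.finite(coup) && coup > 1
  structure(list(
    waveform = obs$waveform, waveform_std = obs$waveform_std,
    control_q99_std = ctl$control_q99_std, coupling = coup,
    significant = sig,
    peak_offset = if (sig) peak_offset(obs$waveform) else NA_real_,
    n_spikes = obs$n_spikes
  ), class = "cd_stapsss")
}

#' STAPSSS coupling table for a whole session
#'
#' Runs the STAPSSS analysis for every unit (firing rate >= `min_rate_hz`)
#' against all four paws and attaches front/hind contralateral bias.
#'
#' @param session A `cd_session`.
#' @param n_shifts Rotations per shift-bootstrap null.
#' @param seed Base seed; each unit x paw combination derives its own.
#' @param threshold Swing threshold, mm per 10 ms.
#' @param min_rate_hz Units below this firing rate are skipped (flagged in
#'   the table with `NA` coupling).
#' @return List with `table` (one row per unit x paw: coupling,
#'   significance, peak offset), `bias` (per unit: front/hind contralateral
#'   bias, see [coupling_and_bias()]) and `waveforms` (201 x units x paws
#'   array).
#' @export
stapsss_session <- function(session, n_shifts = 1000L, seed = 1L,
                            threshold = 0.3, min_rate_hz = 0.1) {
  bins <- bin_spikes(session, 0.01)
  ss <- swing_stance_matrix(session, threshold)
  nu <- nrow(bins)
  rate <- rowSums(bins) / (ncol(bins) * 0.01)
  wf <- array(NA_real_, c(201L, nu, 4L),
              dimnames = list(NULL, session$units$unit_id, PAWS))
  rows <- vector("list", nu * 4L)
  k <- 0L
  for (i in seq_len(nu)) {
    for (p in seq_along(PAWS)) {
      k <- k + 1L
      if (rate[i] < min_rate_hz) {
        rows[[k]] <- data.frame(unit_id = session$units$unit_id[i],
                                paw = PAWS[p], coupling = NA_real_,
                                significant = NA, peak_offset = NA_real_)
        next
      }
      res <- stapsss_unit(bins[i, ], ss[, PAWS[p]], n_shifts = n_shifts,
                          seed = seed + 7L * i + p)
      wf[, i, p] <- res$waveform
      rows[[k]] <- data.frame(unit_id = session$units$unit_id[i],
                              paw = PAWS[p], coupling = res$coupling,
                              significant = res$significant,
                              peak_offset = res$peak_offset)
    }
  }
  tab <- do.call(rbind, rows)
  list(table = tab,
       bias = coupling_and_bias(tab, session$units),
       waveforms = wf)
}

#' Contralateral bias from per-paw couplings
#'
#' The contralateral bias is the ratio of contralateral to ipsilateral paw
#' coupling: `b = c_right / c_left` for left-hemisphere units and
#' `b = c_left / c_right` for right-hemisphere units, computed separately
#' for the front and the hind paw pair. `b` is near 1 for unbiased units.
#'
#' @param coupling_table Data frame with columns `unit_id`, `paw`,
#'   `coupling` (as produced by [stapsss_session()]).
#' @param metadata Unit metadata with columns `unit_id`, `hemisphere`,
#'   `area`.
#' @return Data frame per unit: `unit_id`, `area`, `hemisphere`, `b_front`,
#'   `b_hind` (`NA` where the ipsilateral coupling is 0 or missing).
#' @export
coupling_and_bias <- function(coupling_table, metadata) {
  cw <- function(paw) {
    m <- coupling_table[coupling_table$paw == paw, c("unit_id", "coupling")]
    m$coupling[match(metadata$unit_id, m$unit_id)]
  }
  cfl <- cw("front-left"); cfr <- cw("front-right")
  chl <- cw("hind-left"); chr <- cw("hind-right")
  left <- metadata$hemisphere == "L"
  ratio <- function(contra, ipsi) ifelse(is.na(ipsi) | ipsi == 0,
                                         NA_real_, contra / ipsi)
  data.frame(
    unit_id = metadata$unit_id,
    area = metadata$area, hemisphere = metadata$hemisphere,
    b_front = ifelse(left, ratio(cfr, cfl), ratio(cfl, cfr)),
    b_hind = ifelse(left, ratio(chr, chl), ratio(chl, chr))
  )
}
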