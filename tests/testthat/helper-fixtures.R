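# Shared fixtures, built lazily and cached for the duration of the test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

tiny_arch <- function(seed = 42, ...) archetype_model(seed = seed, ...)

tiny_cfg <- function(n_units = 12L, duration_s = 120, seed = 1L, ...) {
  session_config(n_units = n_units, duration_s = duration_s, seed = seed, ...)
}

tiny_session <- function() {
  cached("tiny_session", generate_session(tiny_arch(), tiny_cfg(seed = 3L)))
}

# small but behaviorally rich session for decoder / embedding smoke tests
small_session <- function() {
  cached("small_session",
         generate_session(tiny_arch(),
                          session_config(n_units = 24L, duration_s = 360,
                                         seed = 5L),
                          subject_seed = 50L))
}

# a hand-built session: two units, known spike times, 0.2 s long is too
# short for the track machinery, so assemble the object directly
manual_session <- function(spike_times, duration_s, n_units = length(spike_times)) {
  n10 <- round(duration_s * 100)
  units <- data.frame(unit_id = sprintf("u%03d", seq_len(n_units)),
                      area = "M1", hemisphere = "L", region = "forelimb",
                      snr = 3, single_unit = TRUE, baseline_hz = 5,
                      swing_gain = 1, latency_s = 0,
                      coupled_paw = "front-right",
                      n_spikes = lengths(spike_times))
  structure(list(units = units, spike_times = spike_times,
                 velocity = matrix(0, n10, 4,
                                   dimnames = list(NULL, c("front-left",
                                                           "front-right",
                                                           "hind-left",
                                                           "hind-right"))),
                 labels = factor(rep("rest", max(1, round(duration_s * 2))),
                                 levels = behavior_classes()),
                 duration_s = duration_s, bin_s = 0.01, snippet_s = 0.5,
                 subject = "T", session_id = "man", seed = 1L),
            class = "cd_session")
}

# brute-force STAPSSS oracle: explicit per-spike window average
brute_stapsss <- function(spike_bins, status) {
  n <- length(status)
  acc <- numeric(201)
  n_sp <- 0
  for (t in seq_len(n)) {
    k <- spike_bins[t]
    if (k > 0 && t > 100 && t <= n - 100) {
      acc <- acc + k * status[(t - 100):(t + 100)]
      n_sp <- n_sp + k
    }
  }
  w <- acc / n_sp
  m <- mean(w)
  if (m > 0) w / m else w
}

# closed-form Procrustes oracle (independent of vegan): translation,
# scale, orthogonal matrix incl. reflection minimizing ||X - s Y Q - t||
oracle_procrustes <- function(X, Y) {
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)
  sv <- svd(t(Xc) %*% Yc)
  Q <- sv$v %*% t(sv$u)
  s <- sum(sv$d) / sum(Yc^2)
  t_vec <- xm - s * as.vector(ym %*% Q)
  list(rotation = Q, scale = s, translation = t_vec,
       Yhat = sweep(s * Y %*% Q, 2, t_vec, `+`))
}

# embedding stub: coordinates with a known snippet labeling
stub_embedding <- function(coords, kept_time_index = seq_len(nrow(coords))) {
  structure(list(coords = coords,
                 eigenvalues = seq_len(ncol(coords)) / ncol(coords),
                 method = "LEM", kept_time_index = kept_time_index,
                 params = list()),
            class = "cd_embedding")
}
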