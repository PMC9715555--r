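#' Shared behavior-archetype model for synthetic populations
#'
#' Defines the latent structure that all subjects drawn from the same model
#' share: one latent archetype vector per behavior class, an area-level map
#' of paw-swing rate gains, and the baseline firing-rate range. Individual
#' subjects sample their own non-negative unit mixtures of the shared
#' archetypes, emulating the situation in which different animals express a
#' common population-level code through different recorded neurons.
#'
#' All distributional choices here are synthetic stand-ins: real recordings
#' provide no generative model, and the generator exists to calibrate and
#' stress the analysis pipeline, not to imitate cortical dynamics.
#'
#' @param latent_dim Dimension of the shared latent space (default 6).
#' @param archetype_separation Non-negative scalar scaling inter-class
#'   archetype distances. 0 means all classes share one archetype (no class
#'   signal).
#' @param swing_gain_by_region Data frame with columns `area`, `hemisphere`,
#'   `gain`: multiplicative firing-rate gain while the unit's contralateral
#'   paw is in swing. Default encodes an anterior-to-posterior gradient
#'   (M2 < M1 < S1), identical in both hemispheres.
#' @param baseline_rate_range Length-2 numeric, min and max baseline rate in
#'   Hz; unit baselines are drawn uniformly from this interval.
#' @param max_rate_hz Hard ceiling on the instantaneous rate (Hz); prevents
#'   Poisson overflow while keeping monotone class tuning.
#' @param swing_latency_s Lag (s) between a swing and the rate modulation it
#'   causes. Positive values make spikes follow movement (sensory-like,
#'   expected spike-triggered offset near `-1000 * swing_latency_s` ms);
#'   negative values make rate lead movement (motor-like).
#' @param movement_gain Strength of a class-shared population activation
#'   axis: all units' rates are scaled by `exp(movement_gain * m_c)` where
#'   `m_c` is the (centered) overall movement level of class c, lowest for
#'   rest. This reproduces the global rest-versus-movement activity
#'   gradient of sensorimotor populations; because it loads all units
#'   equally it carries no unit-identity information.
#' @param seed Integer seed fixing the archetypes.
#' @return An object of class `cd_archetypes`.
#' @export
archetype_model <- function(latent_dim = 6L,
                            archetype_separation = 3.5,
                            swing_gain_by_region = default_swing_gains(),
                            baseline_rate_range = c(2, 12),
                            max_rate_hz = 50,
                            swing_latency_s = 0,
                            movement_gain = 2,
                            seed = 1L) {
  stopifnot(latent_dim >= 1L, archetype_separation >= 0,
            length(baseline_rate_range) == 2L,
            baseline_rate_range[1] > 0,
            baseline_rate_range[2] >= baseline_rate_range[1])
  if (!all(c("area", "hemisphere", "gain") %in% names(swing_gain_by_region)))
    stop("swing_gain_by_region needs columns area, hemisphere, gain")
  if (any(!is.finite(swing_gain_by_region$gain)) ||
      any(swing_gain_by_region$gain < 0))
    stop("swing gains must be finite and >= 0")
  K <- length(CLASSES)
  arch <- with_seed(seed, {
    if (latent_dim >= K) {
      # regular simplex (every class pair equidistant, so the separation
      # parameter controls all inter-class archetype distances at once),
      # embedded orthogonally to the all-ones latent direction: since unit
      # mixing vectors sum to one, this makes the archetypes pure activity
      # *contrasts* -- class identity modulates which units are active,
      # not the average population rate
      s <- svd(diag(K) - 1 / K)
      v <- s$u[, seq_len(K - 1L), drop = FALSE] %*% diag(s$d[seq_len(K - 1L)])
      # anisotropy: a seeded rotation followed by geometrically decaying
      # axis weights gives each archetype model its own class geometry
      # (some pairs close, some far) without letting any pair collapse
      q0 <- qr.Q(qr(matrix(stats::rnorm((K - 1L)^2), K - 1L)))
      v <- v %*% q0 %*% diag(0.7^(0:(K - 2L)))
      v <- v / mean(stats::dist(v))     # mean pairwise distance = 1
      ones <- rep(1, latent_dim) / sqrt(latent_dim)
      B <- qr.Q(qr(cbind(ones, diag(latent_dim))))[, -1L, drop = FALSE]
      q <- qr.Q(qr(matrix(stats::rnorm((latent_dim - 1L)^2),
                          latent_dim - 1L)))
      cbind(v, matrix(0, K, latent_dim - K)) %*% t(q) %*% t(B)
    } else {
      z <- matrix(stats::rnorm(K * latent_dim), K, latent_dim)
      sweep(z, 2, colMeans(z)) / sqrt(2 * latent_dim)
    }
  })
  dimnames(arch) <- list(CLASSES, NULL)
  structure(list(
    latent_dim = latent_dim,
    class_archetypes = archetype_separation * arch,
    archetype_separation = archetype_separation,
    swing_gain_by_region = swing_gain_by_region,
    baseline_rate_range = baseline_rate_range,
    max_rate_hz = max_rate_hz,
    swing_latency_s = swing_latency_s,
    movement_gain = movement_gain,
    seed = seed
  ), class = "cd_archetypes")
}

#' Default area-level swing gains
#'
#' Anterior-to-posterior gradient of paw coupling (M2 < M1 < S1), equal in
#' both hemispheres; gains act on the contralateral paw only, so
#' contralateral bias emerges by construction.
#'
#' @return Data frame with columns `area`, `hemisphere`, `gain`.
#' @export
default_swing_gains <- function() {
  data.frame(
    area = rep(AREAS, each = 2L),
    hemisphere = rep(c("L", "R"), times = 3L),
    gain = rep(c(1.3, 1.8, 2.5), each = 2L)
  )
}

#' Default unit metadata plan
#'
#' Distributes `n_units` over area x hemisphere x somatotopic region
#' (forelimb/hindlimb) as evenly as possible, remainder assigned in order.
#'
#' @param n_units Total number of units.
#' @return Data frame with columns `area`, `hemisphere`, `region`, `n`.
#' @export
default_units_plan <- function(n_units) {
  g <- expand.grid(area = AREAS, hemisphere = c("L", "R"),
                   region = c("forelimb", "hindlimb"),
                   stringsAsFactors = FALSE)
  n <- rep(n_units %/% nrow(g), nrow(g))
  extra <- n_units %% nrow(g)
  if (extra > 0) n[seq_len(extra)] <- n[seq_len(extra)] + 1L
  g$n <- n
  g
}

#' Session configuration for the synthetic generator
#'
#' @param n_units Number of units; must equal the sum of the metadata plan.
#' @param duration_s Session duration in seconds (>= 60).
#' @param units_plan Data frame (`area`, `hemisphere`, `region`, `n`)
#'   giving unit counts per metadata cell; default [default_units_plan()].
#' @param dwell_time_s Named numeric, mean dwell time (s) per behavior class.
#' @param class_weights Named numeric summing to 1, stationary probability of
#'   each class. Defaults emulate the strong class imbalance of spontaneous
#'   behavior (rest and step dominate).
#' @param steps_per_s Mean step rate of a paw during continuous stepping
#'   (stance-to-swing transitions per second; default 1.22).
#' @param swing_speed Mean horizontal speed (mm per 10 ms) of a paw in swing.
#' @param class_gain_sd Standard deviation (log scale) of a session-level
#'   multiplicative rate gain per behavior class, emulating
#'   session-to-session variability in engagement; applied uniformly to
#'   all units, so it perturbs class-level activity signatures without
#'   touching unit-level co-activation structure.
#' @param vigor_sd Standard deviation of a smooth (seconds-timescale)
#'   latent "vigor" process that scales every unit's class-archetype
#'   deviation over time. Behavior is expressed with varying intensity, so
#'   population states form a continuum from a common baseline toward each
#'   class's archetype rather than isolated islands.
#' @param seed Integer seed for this session's behavior and spikes.
#' @return An object of class `cd_session_config`.
#' @export
session_config <- function(n_units = 36L,
                           duration_s = 2160,
                           units_plan = default_units_plan(n_units),
                           dwell_time_s = c(step = 3, turn = 1.5, drink = 2,
                                            groom = 4, rear = 1.5, rest = 4),
                           class_weights = c(step = 0.25, turn = 0.15,
                                             drink = 0.10, groom = 0.10,
                                             rear = 0.10, rest = 0.30),
                           steps_per_s = 1.22,
                           swing_speed = 1.0,
                           class_gain_sd = 0.1,
                           vigor_sd = 0.35,
                           seed = 1L) {
  if (duration_s < 60) stop("duration_s must be >= 60 s")
  unknown <- setdiff(names(class_weights), CLASSES)
  if (length(unknown))
    stop("unknown behavior class: ", paste(unknown, collapse = ", "))
  unknown <- setdiff(names(dwell_time_s), CLASSES)
  if (length(unknown))
    stop("unknown behavior class: ", paste(unknown, collapse = ", "))
  if (abs(sum(class_weights) - 1) > 1e-8)
    stop("class_weights must sum to 1")
  if (sum(units_plan$n) != n_units)
    stop("units_plan counts (", sum(units_plan$n),
         ") do not sum to n_units (", n_units, ")")
  cw <- structure(rep(0, 6), names = CLASSES)
  cw[names(class_weights)] <- class_weights
  dw <- structure(rep(2, 6), names = CLASSES)
  dw[names(dwell_time_s)] <- dwell_time_s
  structure(list(
    n_units = as.integer(n_units), duration_s = duration_s,
    units_plan = units_plan, dwell_time_s = dw, class_weights = cw,
    steps_per_s = steps_per_s, swing_speed = swing_speed,
    class_gain_sd = class_gain_sd, vigor_sd = vigor_sd, seed = seed
  ), class = "cd_session_config")
}

# fraction of the gait cycle a paw group spends in swing, per class
.swing_duty <- function() {
  list(step  = c(front = 0.35, hind = 0.35),
       turn  = c(front = 0.15, hind = 0.05),
       drink = c(front = 0.05, hind = 0.00),
       groom = c(front = 0.25, hind = 0.00),
       rear  = c(front = 0.30, hind = 0.05),
       rest  = c(front = 0.00, hind = 0.00))
}

#' Generate a behavior label track and paw velocity traces
#'
#' Simulates a semi-Markov class sequence on the 500 ms snippet grid
#' (geometric dwell, transition probabilities constructed so that the
#' stationary distribution equals `class_weights` exactly) and paw velocity
#' traces on the 10 ms grid consistent with the labels: during paw-movement
#' classes the paws alternate swing bouts at the configured step rate with
#' speeds above the swing threshold; during rest all speeds stay below it.
#'
#' @param config A [session_config()].
#' @return List with `labels` (factor, one per 500 ms snippet), `velocity`
#'   (matrix, 10 ms rows x 4 paw columns, mm per 10 ms) and `snippet_s`,
#'   `bin_s` clock constants. Snippet `i` covers velocity rows
#'   `(i-1)*50 + 1:50` (half-open bins, shared clock origin).
#' @export
generate_behavior_track <- function(config) {
  stopifnot(inherits(config, "cd_session_config"))
  n_snip <- as.integer(round(config$duration_s / 0.5))
  n_bins <- as.integer(round(config$duration_s * 100))
  w <- config$class_weights
  d <- pmax(1, config$dwell_time_s / 0.5)  # mean dwell in snippets
  with_seed(config$seed, {
    # exit rates w_i/d_i; redistribution a_j chosen so stationary == w exactly
    active <- which(w > 0)
    rate <- w[active] / d[active]
    a <- rate / sum(rate)
    labs <- integer(n_snip)
    cur <- active[sample.int(length(active), 1L, prob = w[active])]
    for (i in seq_len(n_snip)) {
      labs[i] <- cur
      if (stats::runif(1) < 1 / d[cur]) {
        cur <- active[sample.int(length(active), 1L, prob = a)]
      }
    }
    labels <- factor(CLASSES[labs], levels = CLASSES)
    # gait: one swing bout per cycle at steps_per_s cycles/s; each paw's
    # phase advances with its own slowly drifting speed so that paws
    # desynchronize over seconds (real limbs are only loosely phase-locked)
    duty <- .swing_duty()
    offs <- c(`front-left` = 0, `front-right` = 0.5,
              `hind-left` = 0.25, `hind-right` = 0.75)
    lab10 <- rep(labs, each = 50L)[seq_len(n_bins)]
    duty_front <- vapply(duty, `[[`, numeric(1), "front")[lab10]
    duty_hind <- vapply(duty, `[[`, numeric(1), "hind")[lab10]
    vel <- matrix(0, n_bins, 4L, dimnames = list(NULL, PAWS))
    for (p in PAWS) {
      drift <- as.numeric(stats::filter(stats::rnorm(n_bins), 0.995,
                                        "recursive")) * sqrt(1 - 0.995^2)
      incr <- 0.01 * config$steps_per_s * pmax(0.1, 1 + 0.45 * drift)
      phase <- cumsum(incr)
      dy <- if (grepl("front", p)) duty_front else duty_hind
      swing <- ((phase + offs[[p]]) %% 1) < dy
      v <- pmin(abs(stats::rnorm(n_bins, 0, 0.07)), 0.295)
      v[swing] <- pmax(0.31, stats::rnorm(sum(swing), config$swing_speed,
                                          0.2 * config$swing_speed))
      vel[, p] <- v
    }
    list(labels = labels, velocity = vel, snippet_s = 0.5, bin_s = 0.01)
  })
}

#' Sample a subject-specific unit population from a shared archetype model
#'
#' Each unit receives a non-negative random mixing vector over the shared
#' latent space (subject-specific sampling of a common code), a baseline
#' rate drawn uniformly from the model's range, and a swing gain drawn
#' around its area's gain so that paw coupling increases from anterior to
#' posterior areas and acts on the contralateral paw.
#'
#' @param archetypes An [archetype_model()].
#' @param config A [session_config()]; the metadata plan fixes each unit's
#'   area, hemisphere and somatotopic region.
#' @param subject_seed Optional seed overriding `config$seed` for the unit
#'   draw, so several subjects can share one archetype model but differ in
#'   their unit mixtures.
#' @return Data frame with one row per unit: `unit_id`, `area`,
#'   `hemisphere`, `region`, `snr`, `single_unit`, `baseline_hz`,
#'   `swing_gain`, `latency_s`, `coupled_paw`, and the mixing vector in
#'   columns `mix1..mixL`.
#' @export
generate_population <- function(archetypes, config, subject_seed = NULL) {
  stopifnot(inherits(archetypes, "cd_archetypes"),
            inherits(config, "cd_session_config"))
  plan <- config$units_plan
  if (sum(plan$n) != config$n_units)
    stop("units metadata plan inconsistent with n_units")
  seed <- subject_seed %||% config$seed
  with_seed(seed, {
    meta <- plan[rep(seq_len(nrow(plan)), plan$n), c("area", "hemisphere", "region")]
    rownames(meta) <- NULL
    n <- nrow(meta)
    L <- archetypes$latent_dim
    mix <- matrix(abs(stats::rnorm(n * L)), n, L)
    mix <- mix / rowSums(mix)
    gains <- archetypes$swing_gain_by_region
    key <- paste(meta$area, meta$hemisphere)
    gmean <- gains$gain[match(key, paste(gains$area, gains$hemisphere))]
    if (anyNA(gmean)) stop("swing_gain_by_region missing an (area, hemisphere) cell")
    u <- data.frame(
      unit_id = sprintf("u%03d", seq_len(n)),
      meta,
      snr = exp(stats::rnorm(n, log(3), 0.4)),
      single_unit = stats::runif(n) < 0.8,
      baseline_hz = stats::runif(n, archetypes$baseline_rate_range[1],
                                 archetypes$baseline_rate_range[2]),
      swing_gain = pmax(0, stats::rnorm(n, gmean, 0.15)),
      latency_s = archetypes$swing_latency_s,
      stringsAsFactors = FALSE
    )
    # units couple to the contralateral paw of their somatotopic limb
    side <- ifelse(u$hemisphere == "L", "right", "left")
    limb <- ifelse(u$region == "hindlimb", "hind", "front")
    u$coupled_paw <- paste0(limb, "-", side)
    colnames(mix) <- paste0("mix", seq_len(L))
    cbind(u, mix)
  })
}

# per-bin expected rate (Hz) for one unit given expanded class labels (10 ms),
# the unit's coupled-paw swing indicator, and that paw's per-class swing duty.
# The swing term is normalized to unit mean within each class so that class
# identity is encoded in which units co-activate, not in the overall
# population rate (which the somatotopy-shuffle control must not see).
.unit_rate <- function(unit, mix, archetypes, lab10_idx, swing, duty_class,
                       vigor = NULL) {
  pred <- as.vector(archetypes$class_archetypes %*% mix)  # one value per class
  pred <- pmin(pmax(pred, -3), 3)                         # bounded predictor
  pred <- pred - log(mean(exp(pred)))  # baseline_hz = mean rate over classes
  lat_bins <- as.integer(round(unit$latency_s * 100))
  sw <- swing
  if (lat_bins != 0) {
    # positive latency: modulation at t reflects the swing at t - latency
    n <- length(sw)
    sw <- if (lat_bins > 0) c(numeric(min(lat_bins, n)), sw)[seq_len(n)]
    else c(sw[-seq_len(min(-lat_bins, n))], numeric(min(-lat_bins, n)))
  }
  g <- unit$swing_gain
  # class-shared movement-activation axis (identical loading for all units)
  duty <- .swing_duty()
  m <- vapply(duty, mean, numeric(1))
  m <- (archetypes$movement_gain %||% 0) * (m - mean(m))
  z <- pred[lab10_idx]
  if (!is.null(vigor)) z <- pmin(pmax(vigor * z, -3), 3)
  rate <- unit$baseline_hz * exp(z + m[lab10_idx]) *
    (1 + (g - 1) * sw) / (1 + (g - 1) * duty_class[lab10_idx])
  pmin(rate, archetypes$max_rate_hz)
}

#' Generate a full synthetic session
#'
#' Combines [generate_behavior_track()] and [generate_population()] and draws
#' spikes as an inhomogeneous Poisson process in 10 ms bins with rate
#' `baseline * exp(bounded mixing . archetype(class)) * swing-gain term`,
#' clipped at the model's maximum rate. Deterministic given the seeds.
#'
#' @inheritParams generate_population
#' @param subject Subject identifier stored in the session header.
#' @param session_id Session identifier.
#' @param population Optional precomputed [generate_population()] table
#'   (e.g. to share one subject's units across its sessions).
#' @param return_rates If TRUE, attach the per-unit expected-rate matrix
#'   (bins x units, Hz) as attribute `"rates"` for calibration tests.
#' @return A `cd_session` object: `units` metadata table, `spike_times`
#'   (list of numeric vectors, seconds), `velocity` (10 ms grid),
#'   `labels` (500 ms grid), `duration_s`, header fields.
#' @export
generate_session <- function(archetypes, config, subject = "S1",
                             session_id = "ses1", subject_seed = NULL,
                             population = NULL, return_rates = FALSE) {
  track <- generate_behavior_track(config)
  pop <- population %||% generate_population(archetypes, config, subject_seed)
  n_bins <- nrow(track$velocity)
  lab10_idx <- rep(as.integer(track$labels), each = 50L)[seq_len(n_bins)]
  swing_all <- track$velocity > 0.3
  # per-class swing duty of each paw (for the class-mean-neutral swing term)
  duty_mat <- vapply(PAWS, function(p)
    vapply(seq_along(CLASSES), function(ci) {
      sel <- lab10_idx == ci
      if (any(sel)) mean(swing_all[sel, p]) else 0
    }, numeric(1)), numeric(length(CLASSES)))
  mixcols <- grep("^mix", names(pop))
  spikes <- vector("list", nrow(pop))
  rates <- if (return_rates) matrix(NA_real_, n_bins, nrow(pop)) else NULL
  with_seed(config$seed + 1L, {
    class_gain <- exp(stats::rnorm(length(CLASSES), 0,
                                   config$class_gain_sd %||% 0))
    vigor <- NULL
    if ((config$vigor_sd %||% 0) > 0) {
      ar <- as.numeric(stats::filter(stats::rnorm(n_bins), 0.995,
                                     "recursive")) * sqrt(1 - 0.995^2)
      vigor <- pmax(0.2, 1 + config$vigor_sd * ar)
    }
    for (i in seq_len(nrow(pop))) {
      unit <- pop[i, ]
      rate <- class_gain[lab10_idx] *
        .unit_rate(unit, as.numeric(pop[i, mixcols]), archetypes,
                   lab10_idx, swing_all[, unit$coupled_paw],
                   duty_mat[, unit$coupled_paw], vigor)
      if (any(!is.finite(rate)))
        stop("non-finite rate for unit ", unit$unit_id)
      if (return_rates) rates[, i] <- rate
      counts <- stats::rpois(n_bins, rate * 0.01)
      idx <- rep.int(seq_len(n_bins), counts)
      spikes[[i]] <- sort((idx - 1L) * 0.01 + stats::runif(length(idx)) * 0.01)
    }
  })
  pop$n_spikes <- lengths(spikes)
  ses <- structure(list(
    units = pop, spike_times = spikes,
    velocity = track$velocity, labels = track$labels,
    duration_s = config$duration_s, bin_s = 0.01, snippet_s = 0.5,
    subject = subject, session_id = session_id, seed = config$seed
  ), class = "cd_session")
  if (return_rates) attr(ses, "rates") <- rates
  ses
}

#' @export
print.cd_session <- function(x, ...) {
  cat("<cd_session> ", x$subject, "/", x$session_id,
      ": ", nrow(x$units), " units, ", x$duration_s, " s, ",
      length(x$labels), " labeled snippets\n", sep = "")
  invisible(x)
}

#' Bin a session's spikes into counts
#'
#' @param session A `cd_session`.
#' @param bin_s Bin width in seconds (half-open bins `[t, t + bin_s)`).
#' @return Integer matrix, units x bins.
#' @export
bin_spikes <- function(session, bin_s = 0.01) {
  n_bins <- as.integer(round(session$duration_s / bin_s))
  out <- matrix(0L, nrow(session$units), n_bins)
  for (i in seq_along(session$spike_times)) {
    st <- session$spike_times[[i]]
    if (length(st))
      out[i, ] <- tabulate(pmin(floor(st / bin_s) + 1L, n_bins), n_bins)
  }
  rownames(out) <- session$units$unit_id
  out
}
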