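test_that("constant swing status yields a flat, non-significant waveform", {
  n <- 2000L
  sp <- integer(n); sp[c(500L, 900L, 1500L)] <- 1L
  r <- compute_stapsss(sp, rep(1L, n))
  expect_equal(r$waveform, rep(1, 201))
  expect_equal(r$waveform_std, 0)
})

test_that("a single spike reads out its status window exactly", {
  n <- 1200L
  set.seed(3)
  status <- as.integer(runif(n) > 0.7)
  sp <- integer(n); sp[400L] <- 1L
  r <- compute_stapsss(sp, status)
  win <- status[300:500]
  expect_equal(r$waveform, win / mean(win), tolerance = 1e-10)
})

test_that("STAPSSS matches the brute-force window average exactly", {
  set.seed(11)
  for (trial in 1:3) {
    n <- 1000L
    status <- as.integer(runif(n) > 0.5)
    sp <- rpois(n, 0.05)
    if (sum(sp[101:900]) == 0) sp[300] <- 1L
    r <- compute_stapsss(sp, status)
    expect_equal(r$waveform, brute_stapsss(sp, status), tolerance = 1e-8)
  }
})

test_that("time reversal mirrors the waveform", {
  set.seed(5)
  n <- 3000L
  status <- as.integer(runif(n) > 0.6)
  sp <- rpois(n, 0.03)
  if (sum(sp[101:(n - 100)]) == 0) sp[500] <- 1L
  r1 <- compute_stapsss(sp, status)
  r2 <- compute_stapsss(rev(sp), rev(status))
  expect_equal(r2$waveform, rev(r1$waveform), tolerance = 1e-8)
})

test_that("edge cases are rejected with clear errors", {
  expect_error(compute_stapsss(integer(100), integer(100)), "shorter")
  expect_error(compute_stapsss(integer(500), integer(500)), "zero usable")
  sp <- integer(500); sp[50L] <- 1L   # only an edge-clipped spike
  expect_error(compute_stapsss(sp, integer(500)), "zero usable")
  expect_error(shift_null(integer(300), integer(300)), "4 s")
  sp2 <- integer(3000); sp2[1500] <- 1L
  expect_error(shift_null(sp2, integer(3000), n_shifts = 50L), "100")
})

test_that("coupling is invariant to uniform rescaling of the status", {
  set.seed(9)
  n <- 4000L
  status <- as.integer(runif(n) > 0.5)
  sp <- rpois(n, 0.05)
  r1 <- stapsss_unit(sp, status, n_shifts = 200L, seed = 2L)
  r2 <- stapsss_unit(sp, status * 5, n_shifts = 200L, seed = 2L)
  expect_equal(r1$coupling, r2$coupling, tolerance = 1e-10)
  expect_equal(r1$waveform, r2$waveform, tolerance = 1e-10)
})

test_that("the shift null is deterministic under seed", {
  set.seed(13)
  n <- 3000L
  status <- as.integer(runif(n) > 0.4)
  sp <- rpois(n, 0.05)
  a <- shift_null(sp, status, n_shifts = 300L, seed = 7L)
  b <- shift_null(sp, status, n_shifts = 300L, seed = 7L)
  expect_identical(a$control_q99_std, b$control_q99_std)
})

test_that("peak offsets are signed, tie-broken toward zero, and mirrored", {
  w <- rep(1, 201); w[101] <- 2
  expect_equal(peak_offset(w), 0)
  w <- rep(1, 201); w[81] <- 1.5            # 200 ms before the spike
  expect_equal(peak_offset(w), -200)
  expect_equal(peak_offset(rev(w)), 200)
  w <- rep(1, 201); w[c(91, 121)] <- 1.5    # tie: nearer lag wins
  expect_equal(peak_offset(w), -100)
  expect_true(is.na(peak_offset(rep(1, 201))))
})

test_that("a planted modulation latency appears as a negative offset", {
  # rate follows swing with a 200 ms lag -> movement peak precedes spikes
  set.seed(21)
  n <- 60000L
  status <- integer(n)
  o <- 200L
  while (o < n - 400L) {            # jittered swing bouts, ~1 s apart
    status[o:(o + 30L)] <- 1L
    o <- o + sample(70:190, 1L)
  }
  lagged <- c(integer(20L), status)[1:n]
  sp <- rpois(n, 0.02 * (1 + 4 * lagged))
  r <- stapsss_unit(sp, status, n_shifts = 300L, seed = 3L)
  expect_true(r$significant)
  expect_lt(r$peak_offset, -100)
  expect_gt(r$peak_offset, -320)
})

test_that("contralateral bias follows its definition", {
  tab <- data.frame(unit_id = rep(c("a", "b"), each = 4),
                    paw = rep(c("front-left", "front-right",
                                "hind-left", "hind-right"), 2),
                    coupling = c(1, 2, 1, 1, 2, 1, 1, 0))
  meta <- data.frame(unit_id = c("a", "b"), hemisphere = c("L", "R"),
                     area = c("S1", "M1"))
  b <- coupling_and_bias(tab, meta)
  expect_equal(b$b_front[b$unit_id == "a"], 2)   # left hemi: c_r / c_l
  expect_equal(b$b_hind[b$unit_id == "a"], 1)
  expect_equal(b$b_front[b$unit_id == "b"], 2)   # right hemi: c_l / c_r
  expect_true(is.na(b$b_hind[b$unit_id == "b"])) # ipsilateral coupling 0
})
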