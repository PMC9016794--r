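test_that("period estimation on sampled sinusoids is accurate to 0.01 h", {
  for (T in c(6, 12, 19.1, 24, 30)) {
    tr <- sine_traj(T)
    pe <- estimate_period(tr, "x", discard = T)
    expect_lt(abs(pe$period - T), 0.01)
    expect_lt(pe$sd, 0.01)
    expect_gte(pe$n_cycles, 3)
  }
})

test_that("flat and too-short signals raise the documented errors", {
  t <- seq(0, 100, by = 0.05)
  flat <- synthetic_traj(t, x = rep(0.5, length(t)), y = rep(1, length(t)))
  expect_error(estimate_period(flat, "x"), "steady state")
  expect_equal(classify_regime(flat), "steady_state")
  short <- sine_traj(24, t_end = 50)
  expect_error(estimate_period(short, "x", discard = 0), "fewer than 3")
  expect_error(classify_regime(short), "insufficient")
})

test_that("regime classification separates simple, period-2 and aperiodic", {
  expect_equal(classify_regime(sine_traj(24, t_end = 400)), "periodic")
  expect_equal(classify_regime(period2_traj()), "complex_periodic")
  ## quasiperiodic two-tone signal: neither simple nor short-pattern
  t <- seq(0, 600, by = 0.05)
  qp <- synthetic_traj(t, x = sin(2 * pi * t / 24) +
                         0.8 * sin(2 * pi * t / (24 * (1 + sqrt(5)) / 2)),
                       y = cos(2 * pi * t / 24))
  expect_equal(classify_regime(qp, "x"), "aperiodic")
})

test_that("normal-form stable cycles always classify as periodic", {
  nf <- make_normal_form(c(1, 2, 3))
  set.seed(7)
  for (i in 1:10) {
    r0 <- sample(c(runif(1, 0.3, 1.9), runif(1, 2.1, 3.6)), 1)
    th <- runif(1, 0, 2 * pi)
    tr <- integrate_model(nf, c(r0 * cos(th), r0 * sin(th)), 0, 400,
                          default_cfg)
    expect_equal(classify_regime(tr, discard = 250), "periodic",
                 info = sprintf("r0 = %.3f", r0))
  }
})

test_that("fingerprints capture amplitude and are reproducible across basins", {
  nf <- make_normal_form(c(1, 2, 3))
  tr <- integrate_model(nf, c(1, 0), 0, 300, default_cfg)
  fp <- fingerprint(tr, discard = 150)
  ## a radius-1 rotation spans [-1, 1] in both planar variables
  expect_equal(unname(fp$amplitude), c(2, 2), tolerance = 1e-3)
  expect_true(all(fp$waveform >= 0 & fp$waveform <= 1))
  expect_equal(nrow(fp$waveform), 256)
  ## same attractor reached from two different starts: near-zero distance
  tr2 <- integrate_model(nf, c(0.4, 0.7), 0, 600, default_cfg)
  fp2 <- fingerprint(tr2, discard = 450)
  expect_lt(attractor_distance(fp, fp2), 0.01)
  ## different attractors: far apart (amplitudes differ 3-fold)
  tr3 <- integrate_model(nf, c(3, 0), 0, 300, default_cfg)
  fp3 <- fingerprint(tr3, discard = 150)
  expect_gt(attractor_distance(fp, fp3), 0.5)
})

test_that("non-periodic regimes are not fingerprintable", {
  expect_error(fingerprint(period2_traj()), "not fingerprintable")
})

test_that("attractor distance is a shift-invariant semimetric", {
  a <- toy_fingerprint(24)
  expect_equal(attractor_distance(a, a), 0)
  b <- toy_fingerprint(26)
  expect_equal(attractor_distance(a, b), attractor_distance(b, a))
  expect_gte(attractor_distance(a, b), 0)
  ## cyclic shift by a whole number of grid points: distance exactly 0
  on_grid <- toy_fingerprint(24, shift = 77 / 256)
  expect_lt(attractor_distance(a, on_grid), 1e-9)
  ## shift between grid points: distance bounded by the resampling error
  off_grid <- toy_fingerprint(24, shift = 0.3)
  expect_lt(attractor_distance(a, off_grid), 0.01)
  ## the documented period-separation example: 22.99 vs 23.52 h with
  ## identical waveforms
  d <- attractor_distance(toy_fingerprint(22.99), toy_fingerprint(23.52))
  expect_equal(d, (23.52 - 22.99) / 22.99, tolerance = 1e-9)
  ## mismatched variable sets are rejected
  odd <- toy_fingerprint(24)
  odd$var_labels <- c("a", "b")
  expect_error(attractor_distance(a, odd), "mismatched")
})

test_that("amplitude separates concentric cycles that share period and shape", {
  small <- toy_fingerprint(24, amp = 1)
  big <- toy_fingerprint(24, amp = 3)
  expect_gt(attractor_distance(small, big), 0.5)
})

test_that("distances are stable under waveform-grid refinement", {
  nf <- make_normal_form(c(1, 2, 3))
  tr1 <- integrate_model(nf, c(1, 0), 0, 300, default_cfg)
  tr2 <- integrate_model(nf, c(0.4, 0.7), 0, 600, default_cfg)
  d <- vapply(c(256, 512), function(W) {
    attractor_distance(fingerprint(tr1, discard = 150, W = W),
                       fingerprint(tr2, discard = 450, W = W))
  }, numeric(1))
  expect_lt(abs(d[1] - d[2]), 0.001)
})

test_that("steady states compare only with steady states", {
  st <- steady_fingerprint(c(x = 0.5, y = 0.1))
  expect_equal(attractor_distance(st, st), 0)
  expect_equal(attractor_distance(st, steady_fingerprint(c(x = 2, y = 1))) > 0.1,
               TRUE)
  expect_true(is.infinite(attractor_distance(st, toy_fingerprint(24))))
})

test_that("sync detection finds 1:1 and 1:2 locks and rejects detuning", {
  t <- seq(0, 800, by = 0.05)
  same <- synthetic_traj(t, A = sin(2 * pi * t / 24),
                         B = cos(2 * pi * t / 24))
  s11 <- check_sync(same, "A", "B", discard = 100)
  expect_true(s11$locked)
  expect_equal(c(s11$p, s11$q), c(1L, 1L))
  expect_equal(s11$common_period, 24, tolerance = 0.01)
  ## B twice as fast as A: frequency ratio 1:2
  half <- synthetic_traj(t, A = sin(2 * pi * t / 24),
                         B = sin(2 * pi * t / 12))
  s12 <- check_sync(half, "A", "B", discard = 100)
  expect_true(s12$locked)
  expect_equal(c(s12$p, s12$q), c(1L, 2L))
  ## golden-ratio detuned pair: no small-integer lock
  phi <- (1 + sqrt(5)) / 2
  det <- synthetic_traj(t, A = sin(2 * pi * t / 24),
                        B = sin(2 * pi * t / (24 * phi)))
  expect_false(check_sync(det, "A", "B", discard = 100)$locked)
  ## a suppressed oscillator yields a flagged, not-applicable result
  supp <- synthetic_traj(t, A = sin(2 * pi * t / 24),
                         B = rep(0.2, length(t)))
  s_na <- check_sync(supp, "A", "B", discard = 100)
  expect_false(s_na$applicable)
  expect_false(s_na$locked)
})
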