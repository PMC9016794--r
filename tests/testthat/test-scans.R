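test_that("mode clustering separates the documented period triple", {
  ## periods 22.99, 23.52, 26.43 h with identical normalized waveforms:
  ## smallest pairwise relative gap is (23.52 - 22.99)/22.99 = 2.3%,
  ## far above the 1% threshold
  fps <- list(toy_fingerprint(22.99), toy_fingerprint(26.43),
              toy_fingerprint(23.52))
  cl <- cluster_modes(fps, threshold = 0.01)
  expect_length(cl$representatives, 3)
  ## cluster ids ordered by ascending period
  expect_equal(vapply(cl$representatives, `[[`, numeric(1), "period"),
               c(22.99, 23.52, 26.43))
  expect_equal(cl$assignment, c(1L, 3L, 2L))
})

test_that("mode clustering merges identical fingerprints and is
           permutation invariant", {
  fps <- list(toy_fingerprint(24), toy_fingerprint(24),
              toy_fingerprint(26), toy_fingerprint(24, shift = 0.4))
  cl <- cluster_modes(fps, threshold = 0.01)
  expect_length(cl$representatives, 2)
  expect_equal(cl$assignment, c(1L, 1L, 2L, 1L))
  perm <- c(3, 1, 4, 2)
  cl_p <- cluster_modes(fps[perm], threshold = 0.01)
  expect_equal(cl_p$assignment, cl$assignment[perm])
  expect_error(cluster_modes(list()), "no fingerprints")
})

test_that("initial-condition census matches the trirhythmic oracle exactly", {
  radii <- c(0.5, 1.0, 1.5, 2.0, 2.5)
  nf <- make_normal_form(radii, shear = 0.01)
  ## grid chosen off the unstable circles at r = 1 and r = 2, where the
  ## basin prediction is degenerate
  ic_r <- seq(0.2, 3.2, length.out = 15)
  census <- mode_census_ic(nf, lapply(ic_r, function(r) c(x = r, y = 0)),
                           t_end = 400, cfg = default_cfg)
  expect_equal(census$classification, "tri")
  expect_length(census$modes, 3)
  ## periods within 0.1% of 2*pi/(omega0 + beta rho^2)
  T_exact <- sort(2 * pi / (2 * pi / 24 + 0.01 * c(0.5, 1.5, 2.5)^2))
  expect_equal(mode_periods(census), T_exact, tolerance = 1e-3)
  ## per-run assignment equals the radial sign analysis
  expected_rho <- vapply(ic_r, function(r) normal_form_basin_of(nf, r),
                         numeric(1))
  ## modes are ordered by ascending period = descending radius here
  mode_rho <- vapply(census$modes, function(f) f$amplitude[["x"]] / 2,
                     numeric(1))
  expect_equal(mode_rho[census$assignment$mode], expected_rho,
               tolerance = 1e-2)
  ## basin fractions partition the synchronized runs
  expect_equal(sum(census$basin_fraction), 1, tolerance = 1e-9)
})

test_that("onset sweeps are deterministic and label unsynchronized runs", {
  gw <- make_goodwin_clock(); ck <- make_cdk_cycle()
  strong <- make_coupled(gw, ck, strong_coupling_spec())
  a <- onset_sweep(strong, 1000, 1002, dt_c = 0.5, cfg = default_cfg,
                   post_discard = 600, post_window = 300)
  b <- onset_sweep(strong, 1000, 1002, dt_c = 0.5, cfg = default_cfg,
                   post_discard = 600, post_window = 300)
  expect_identical(a$assignment, b$assignment)
  expect_equal(a$classification, "mono")
  expect_true(all(a$assignment$p == 1 & a$assignment$q == 1))
  ## neutral coupling with incommensurate free periods: no p:q <= 4 lock
  ## (24/19.1 is more than 1% away from every such ratio)
  ratios <- outer(1:4, 1:4, "/")
  expect_gt(min(abs(ratios - 24 / 19.1) / (24 / 19.1)), 0.01)
  neutral <- make_coupled(gw, ck, coupling_spec(0, 1e6, t_c = 1000))
  n <- onset_sweep(neutral, 1000, 1002, dt_c = 0.5, cfg = default_cfg,
                   post_discard = 600, post_window = 300)
  expect_equal(n$classification, "none")
  expect_true(all(n$assignment$status == "unsynchronized"))
})

test_that("the onset grid is inclusive with the documented cardinality", {
  ## 1000 to 1030 by 0.05 spans 601 runs
  expect_equal(length(seq(1000, 1030, by = 0.05)), 601)
  gw <- make_goodwin_clock(); ck <- make_cdk_cycle()
  strong <- make_coupled(gw, ck, strong_coupling_spec())
  cen <- onset_sweep(strong, 1000, 1000.2, dt_c = 0.05, cfg = default_cfg,
                     post_discard = 600, post_window = 300)
  expect_equal(cen$assignment$t_c, seq(1000, 1000.2, by = 0.05))
})

test_that("synchronization diagram classifies corner cells correctly", {
  gw <- make_goodwin_clock(); ck <- make_cdk_cycle()
  dg <- synchronization_diagram(gw, ck, v_sw_grid = c(0, 2),
                                K_ICdk1_grid = c(5, 1000),
                                n_onset = 5, cfg = default_cfg,
                                post_discard = 600, post_window = 300)
  cells <- dg$cells
  expect_equal(nrow(cells), 4)
  ## weak-repression, no-induction cell: free periods stay incommensurate
  expect_equal(cells$classification[cells$v_sw == 0 &
                                      cells$K_ICdk1 == 1000], "none")
  ## strong induction locks 1:1 regardless of repression strength here
  expect_true(all(cells$classification[cells$v_sw == 2] == "mono"))
  ## any stored mode period is reproducible by a targeted rerun
  cell <- which(cells$v_sw == 2 & cells$K_ICdk1 == 5)
  stored <- mode_periods(dg$censuses[[cell]])
  rerun <- onset_sweep(make_coupled(gw, ck, coupling_spec(2, 5)),
                       1000, 1030, dt_c = 30 / 4, cfg = default_cfg,
                       post_discard = 600, post_window = 300)
  expect_equal(mode_periods(rerun), stored, tolerance = 1e-6)
  expect_error(synchronization_diagram(gw, ck, c(2, 1), c(1, 2)),
               "increasing")
})

test_that("hysteresis sweep recovers the closed-form bistable window", {
  ## radial fixture dr/dt = -k r (r^2-1)((r^2-c)^2 - mu), c = 4:
  ## two stable cycles (r = 1, r = sqrt(4 + sqrt(mu))) exactly for mu in
  ## (0, mu_max]; the grid below steps by 0.125 so 0.25 is a grid point
  m <- make_ring_hysteresis(c_center = 4, mu = 0.25)
  hy <- hysteresis_sweep(m, "mu", -0.5, 1, n_steps = 13, settle = 300,
                         y0 = c(x = 1, y = 0),
                         y0_backward = c(x = sqrt(5), y = 0),
                         cfg = default_cfg)
  ## forward branch never leaves r = 1
  expect_true(all(vapply(hy$forward, function(f)
    abs(f$amplitude[["x"]] - 2) < 0.02, logical(1))))
  ## disagreement window = (0, 1] within one grid step
  step <- diff(hy$grid)[1]
  expect_lte(abs(min(hy$grid[hy$disagree]) - step / 2), step)
  expect_equal(max(hy$grid[hy$disagree]), 1)
  expect_false(any(hy$disagree[hy$grid < -step / 2]))
  ## outer-branch amplitude at mu = 0.25 equals sqrt(4 + sqrt(0.25))
  i <- which(abs(hy$grid - 0.25) < 1e-9)
  expect_equal(hy$backward[[i]]$amplitude[["x"]] / 2, sqrt(4.5),
               tolerance = 0.01)
})

test_that("a monostable parameter range shows no hysteresis", {
  m <- make_ring_hysteresis(c_center = 4, mu = -0.3)
  hy <- hysteresis_sweep(m, "mu", -0.5, -0.1, n_steps = 5, settle = 250,
                         y0 = c(x = 1, y = 0),
                         y0_backward = c(x = 2.1, y = 0),
                         cfg = default_cfg)
  expect_null(hy$disagreement_window)
})

test_that("entrainment map: null row unlocked, tongue widens with amplitude", {
  gw <- make_goodwin_clock()
  map <- arnold_map(gw, "v1",
                    period_grid = c(21.5, 22.5, 23.0, 23.5, 24.5, 25.0, 26.0),
                    amplitude_grid = c(0, 0.15, 0.4),
                    n_phases = 1, y0 = goodwin_init_state(),
                    cfg = default_cfg)
  zero <- subset(map$cells, amplitude == 0)
  expect_false(any(zero$locked))
  tw <- tongue_width(map)
  expect_true(all(diff(tw$width) >= 0))
  expect_gt(tw$width[nrow(tw)], 0)
})

test_that("pulse-switch map reproduces the analytic basin crossings", {
  nf <- make_normal_form(c(1, 2, 3))
  census <- mode_census_ic(nf, list(c(x = 1, y = 0), c(x = 3, y = 0)),
                           t_end = 400, cfg = default_cfg)
  sm <- pulse_switch_map(nf, c(x = 1, y = 0), "x",
                         phase_grid = c(0, 0.25, 0.5, 0.75),
                         magnitude_grid = c(0, 0.5, 1.5, 2.5, 3.5),
                         modes = census$modes, cfg = default_cfg)
  expect_equal(sm$source_mode, "M1")
  ## zero-magnitude row maps every phase to the source mode
  expect_true(all(sm$cells$destination[sm$cells$magnitude == 0] == "M1"))
  ## per-cell analytic prediction from the recorded source states:
  ## post-pulse radius above/below the unstable circle at r = 2
  pred <- mapply(function(ph, mg) {
    st <- sm$source_states[match(ph, sm$phase_grid), ]
    if (sqrt((st[["x"]] + mg)^2 + st[["y"]]^2) < 2) "M1" else "M2"
  }, sm$cells$phase, sm$cells$magnitude)
  expect_equal(sm$cells$destination, unname(pred))
})
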