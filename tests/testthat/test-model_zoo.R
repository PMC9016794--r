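test_that("normal-form construction validates its arguments", {
  expect_error(make_normal_form(c(1, 2)), "odd")
  expect_error(make_normal_form(c(1, 3, 2)), "increasing")
  expect_error(make_normal_form(c(1, 2, 3), omega0 = -1), "omega0")
  expect_error(make_normal_form(c(1, 2, 3), relax = 0), "relax")
})

test_that("normal-form attractor table matches the closed form", {
  ## T = 2*pi / (omega0 + beta * rho^2), computed independently here
  omega0 <- 2 * pi / 24
  nf <- make_normal_form(c(0.5, 1.0, 1.5, 2.0, 2.5), shear = 0.01)
  att <- normal_form_attractors(nf)
  expect_equal(att$radius, c(0.5, 1.0, 1.5, 2.0, 2.5))
  expect_equal(att$stable, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(att$period, 2 * pi / (omega0 + 0.01 * att$radius^2))
  ## the shipped example values for the three stable cycles
  expect_equal(att$period[att$stable], c(23.772, 22.101, 19.375),
               tolerance = 1e-4)
})

test_that("measured normal-form periods and amplitudes match theory", {
  nf <- make_normal_form(c(0.5, 1.0, 1.5, 2.0, 2.5), shear = 0.01)
  att <- normal_form_attractors(nf)
  for (rho in att$radius[att$stable]) {
    tr <- integrate_model(nf, c(rho, 0), 0, 300, default_cfg)
    pe <- estimate_period(tr, "x", discard = 100)
    T_exact <- att$period[att$radius == rho]
    expect_lt(abs(pe$period - T_exact) / T_exact, 1e-3)
    fp <- fingerprint(tr, discard = 100)
    expect_lt(abs(fp$amplitude[["x"]] / 2 - rho) / rho, 1e-2)
    expect_lt(abs(fp$amplitude[["y"]] / 2 - rho) / rho, 1e-2)
  }
})

test_that("basin prediction agrees with the 1-D radial brute-force oracle", {
  radii <- c(0.5, 1.0, 1.5, 2.0, 2.5)
  nf <- make_normal_form(radii, shear = 0.01)
  set.seed(42)
  for (r0 in runif(12, 0.1, 3.2)) {
    expect_equal(normal_form_basin_of(nf, r0),
                 radial_oracle_attractor(radii, r0),
                 info = sprintf("r0 = %g", r0))
  }
  ## the documented case: r0 = 1.2 lies between unstable radii 1 and 2
  expect_equal(normal_form_basin_of(nf, 1.2), 1.5)
})

test_that("clock stand-in free-runs at 24 h and obeys exact time rescaling", {
  gw <- make_goodwin_clock()
  tr <- integrate_model(gw, goodwin_init_state(), 0, 1500, default_cfg)
  pe <- estimate_period(tr, "P", discard = 1000)
  expect_lt(abs(pe$period - 24), 0.1)
  expect_equal(classify_regime(tr, "P", discard = 1000), "periodic")
  ## doubling tau doubles the measured period
  gw2 <- make_goodwin_clock(time_scale = 2 * multisync:::GOODWIN_TAU)
  tr2 <- integrate_model(gw2, goodwin_init_state(), 0, 3000, default_cfg)
  pe2 <- estimate_period(tr2, "P", discard = 2000)
  expect_lt(abs(pe2$period - 2 * pe$period), 0.05)
})

test_that("full mitotic repression silences clock transcription", {
  gw <- make_goodwin_clock()
  tr <- integrate_model(gw, goodwin_init_state(), 0, 800, default_cfg,
                        ports = list(R = 0))
  expect_equal(classify_regime(tr, "M", discard = 500), "steady_state")
  ## M has decayed to (numerically) nothing
  expect_lt(max(traj_var(traj_window(tr, from = 500), "M")), 1e-3)
})

test_that("ports absent and ports at neutral defaults are the same system", {
  gw <- make_goodwin_clock()
  tr_a <- integrate_model(gw, goodwin_init_state(), 0, 200, default_cfg)
  tr_b <- integrate_model(gw, goodwin_init_state(), 0, 200, default_cfg,
                          ports = list(R = 1))
  expect_identical(tr_a$state, tr_b$state)
})

test_that("cell-cycle stand-in free-runs at 19.1 h and rescales with eps", {
  ck <- make_cdk_cycle()
  tr <- integrate_model(ck, cdk_init_state(), 0, 1200, default_cfg)
  pe <- estimate_period(tr, "A", discard = 800)
  expect_lt(abs(pe$period - 19.1), 0.2)
  ## scaling eps by c scales the period by c
  ck15 <- make_cdk_cycle(eps = 1.5 * multisync:::CDK_EPS_REF)
  tr15 <- integrate_model(ck15, cdk_init_state(), 0, 1800, default_cfg)
  pe15 <- estimate_period(tr15, "A", discard = 1200)
  expect_lt(abs(pe15$period - 1.5 * pe$period), 0.05)
})

test_that("saturating Wee1 induction suppresses the Cdk1 oscillation", {
  ck <- set_param(make_cdk_cycle(), "vsw", 8)
  tr <- integrate_model(ck, cdk_init_state(), 0, 900, default_cfg,
                        ports = list(S = 1))
  expect_equal(classify_regime(tr, "A", discard = 600), "steady_state")
})

test_that("coupling spec validates and the Hill identities hold", {
  expect_error(coupling_spec(v_sw = -1, K_ICdk1 = 1), "v_sw")
  expect_error(coupling_spec(v_sw = 1, K_ICdk1 = 0), "K_ICdk1")
  expect_error(coupling_spec(v_sw = 1, K_ICdk1 = 1, h_w = 0.5), "Hill")
  ## half-saturation identity R = 1/2 at A = K_ICdk1, for any exponent
  for (g in c(1, 2, 4, 7))
    expect_equal(mitotic_repression(0.65, 0.65, g), 0.5)
  expect_equal(wee1_induction(0.5, v_sw = 2, K_w = 0.5, h_w = 4), 1)
  expect_equal(mitotic_repression(0, 0.65, 2), 1)
})

test_that("coupled system echoes the coupling constants in its manifest", {
  cs <- make_coupled(make_goodwin_clock(), make_cdk_cycle(),
                     coupling_spec(v_sw = 2.3, K_ICdk1 = 0.65, t_c = 1000))
  m <- model_manifest(cs)
  expect_equal(m$coupling$v_sw, 2.3)
  expect_equal(m$coupling$K_ICdk1, 0.65)
  expect_equal(m$coupling$t_c, 1000)
  expect_equal(cs$n_vars, 3 + 4)
})

test_that("neutral coupling reproduces the uncoupled trajectories", {
  gw <- make_goodwin_clock()
  ck <- make_cdk_cycle()
  cs <- make_coupled(gw, ck, coupling_spec(v_sw = 0, K_ICdk1 = 1e6, t_c = 0))
  tr <- integrate_model(cs, c(goodwin_init_state(), cdk_init_state()),
                        0, 250, default_cfg)
  tg <- integrate_model(gw, goodwin_init_state(), 0, 250, default_cfg)
  tc <- integrate_model(ck, cdk_init_state(), 0, 250, default_cfg)
  expect_lt(max(abs(tr$state[, 1:3] - tg$state)), 1e-4)
  expect_lt(max(abs(tr$state[, 4:7] - tc$state)), 1e-4)
})

test_that("compiled and interpreted right-hand sides agree", {
  cfg_r <- integrator_config(use_compiled = FALSE)
  for (model in list(make_normal_form(c(1, 2, 3)),
                     make_goodwin_clock(),
                     make_cdk_cycle(),
                     make_coupled(make_goodwin_clock(), make_cdk_cycle(),
                                  coupling_spec(2.3, 0.65, t_c = 0)))) {
    y0 <- switch(model$name,
                 normal_form_m3 = c(1.4, 0),
                 goodwin_clock = goodwin_init_state(),
                 cdk_cycle = cdk_init_state(),
                 c(goodwin_init_state(), cdk_init_state()))
    a <- integrate_model(model, y0, 0, 60, default_cfg)
    b <- integrate_model(model, y0, 0, 60, cfg_r)
    expect_lt(max(abs(a$state - b$state)), 1e-5)
  }
})

test_that("coupled construction rejects missing ports", {
  nf <- make_normal_form(c(1, 2, 3))
  expect_error(make_coupled(nf, make_cdk_cycle(), coupling_spec(1, 1)),
               "port")
  expect_error(make_coupled(make_goodwin_clock(), nf, coupling_spec(1, 1)),
               "port")
})

test_that("periodic forcing: null amplitude, square levels, mean preservation", {
  gw <- make_goodwin_clock()
  ## amplitude 0 leaves the model unchanged
  f0 <- make_forced(gw, forcing_spec("v1", "sinusoid", period = 24,
                                     amplitude = 0))
  a <- integrate_model(gw, goodwin_init_state(), 0, 150, default_cfg)
  b <- integrate_model(f0, goodwin_init_state(), 0, 150, default_cfg)
  expect_lt(max(abs(a$state - b$state)), 1e-8)
  ## square waveform: alternates between the two levels every half period,
  ## cycle mean preserved at the baseline
  fs <- forcing_spec("v1", "square", period = 24, amplitude = 0.2,
                     duty = 0.5)
  v_hi <- forcing_value(fs, 0.7, 3)
  v_lo <- forcing_value(fs, 0.7, 15)
  expect_equal(v_hi, 0.7 + 0.2 * 0.5)
  expect_equal(v_lo, 0.7 - 0.2 * 0.5)
  tt <- seq(0, 48, by = 0.1)
  expect_equal(mean(forcing_value(fs, 0.7, tt[-length(tt)])), 0.7,
               tolerance = 1e-9)
  ## switching happens at 12 h with duty 0.5
  expect_equal(forcing_value(fs, 0.7, 11.9), v_hi)
  expect_equal(forcing_value(fs, 0.7, 12.1), v_lo)
  ## a square excursion driving the parameter negative is rejected
  expect_error(make_forced(gw, forcing_spec("v1", "square", period = 24,
                                            amplitude = 2, duty = 0.5)),
               "negative")
})

test_that("resonant forcing at the free-running period locks 1:1", {
  gw <- make_goodwin_clock()
  forced <- make_forced(gw, forcing_spec("v1", "sinusoid", period = 24,
                                         amplitude = 0.15))
  tr <- integrate_model(forced, goodwin_init_state(), 0, 900, default_cfg)
  pe <- estimate_period(tr, "P", discard = 600)
  expect_lt(abs(pe$period - 24) / 24, 1e-2)
  expect_equal(classify_regime(tr, "P", discard = 600), "periodic")
})
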