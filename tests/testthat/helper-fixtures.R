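## shared fixtures, built in code

default_cfg <- integrator_config()

## a trajectory object from an analytic signal x(t) (plus optional extra
## columns), bypassing the integrator
synthetic_traj <- function(t, ..., labels = NULL) {
  cols <- list(...)
  state <- do.call(cbind, cols)
  if (is.null(labels)) labels <- names(cols)
  colnames(state) <- labels
  multisync:::new_trajectory(t, state, labels, list())
}

sine_traj <- function(period, t_end = 12 * period, dt = 0.05, phase = 0) {
  t <- seq(0, t_end, by = dt)
  synthetic_traj(t, x = sin(2 * pi * (t / period) + phase),
                 y = cos(2 * pi * (t / period) + phase))
}

## alternating-peak-height signal: period-2 pattern (heights 1, 0.6, 1, ...)
period2_traj <- function(base_period = 24, t_end = 480, dt = 0.05) {
  t <- seq(0, t_end, by = dt)
  x <- sin(2 * pi * t / base_period) *
    ifelse((t %/% base_period) %% 2 == 0, 1, 0.6)
  synthetic_traj(t, x = x, y = cos(2 * pi * t / base_period))
}

## brute-force oracle for the radial flow dr/dt = -k r Q(r^2): 1-D
## integration, independent of the package's planar path
radial_oracle_attractor <- function(radii, r0, k = 1e-2, t_end = 2000) {
  rhs <- function(t, r, p) {
    u <- r^2
    list(-k * r * prod(u - radii^2))
  }
  out <- deSolve::ode(y = r0, times = c(0, t_end), func = rhs, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  r_inf <- out[nrow(out), 2]
  stable <- radii[seq_along(radii) %% 2 == 1]
  stable[which.min(abs(stable - r_inf))]
}

## a minimal hand-made fingerprint for clustering tests
toy_fingerprint <- function(period, amp = 1, shift = 0, W = 256) {
  g <- 2 * pi * ((0:(W - 1)) / W + shift)
  wf <- cbind(x = (sin(g) + 1) / 2, y = (cos(g) + 1) / 2)
  structure(list(period = period,
                 amplitude = c(x = 2 * amp, y = 2 * amp),
                 waveform = wf, W = W, regime = "periodic",
                 variable = "x", var_labels = c("x", "y")),
            class = "attractor_fingerprint")
}
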