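#' Construct an autonomous oscillator model
#'
#' The basic container for a named ODE system. A model owns its state-variable
#' labels, a named parameter vector, a global time-scale factor that divides
#' every rate, named input ports (exogenous signals with neutral defaults, so
#' that the model is autonomous when ports are left alone) and named output
#' ports (readout variables other models or analyses can tap).
#'
#' The derivative contract is `rhs(t, y, params, ports)`, returning the
#' rate-of-change vector *before* division by `time_scale`; the integration
#' engine applies the division. This makes the exact time-rescaling property
#' (multiplying `time_scale` by c multiplies every period by c) hold by
#' construction for every model.
#'
#' @param name short identifier.
#' @param var_labels character vector of state-variable names.
#' @param params named numeric parameter vector.
#' @param rhs derivative function `(t, y, params, ports) -> numeric`.
#' @param time_scale positive scalar dividing every rate (dimensionless).
#' @param var_units character vector of units, recycled if length 1.
#' @param input_ports named numeric vector of neutral port defaults.
#' @param output_ports named character vector mapping port name to variable.
#' @param nominal_period optional free-running period metadata (h).
#' @param nonneg logical vector; TRUE for variables that are concentrations
#'   and must stay non-negative.
#' @param compiled optional list `(func, initfunc, parms)` pointing at a
#'   compiled right-hand side; `parms(model, ports)` must build the numeric
#'   parameter vector the C routine expects.
#' @return an object of class `oscillator_model`.
#' @export
oscillator_model <- function(name, var_labels, params, rhs,
                             time_scale = 1, var_units = "dimensionless",
                             input_ports = numeric(0),
                             output_ports = character(0),
                             nominal_period = NULL,
                             nonneg = FALSE,
                             compiled = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  n_vars <- length(var_labels)
  if (n_vars < 2) stop("an oscillator model needs at least 2 state variables")
  if (!is.numeric(time_scale) || length(time_scale) != 1 || time_scale <= 0)
    stop("time_scale must be a positive scalar")
  if (!is.function(rhs)) stop("rhs must be a function(t, y, params, ports)")
  if (length(var_units) == 1) var_units <- rep(var_units, n_vars)
  if (length(nonneg) == 1) nonneg <- rep(nonneg, n_vars)
  stopifnot(length(var_units) == n_vars, length(nonneg) == n_vars)
  if (length(input_ports) && is.null(names(input_ports)))
    stop("input_ports must be named")
  bad <- setdiff(unname(output_ports), var_labels)
  if (length(bad))
    stop("output_ports refer to unknown variables: ", paste(bad, collapse = ", "))
  structure(list(
    name = name, n_vars = n_vars, var_labels = var_labels,
    var_units = var_units, params = params, rhs = rhs,
    time_scale = time_scale, input_ports = input_ports,
    output_ports = output_ports, nominal_period = nominal_period,
    nonneg = nonneg, compiled = compiled
  ), class = "oscillator_model")
}

#' @export
print.oscillator_model <- function(x, ...) {
  cat(sprintf("<oscillator_model '%s'> %d variables: %s\n", x$name, x$n_vars,
              paste(x$var_labels, collapse = ", ")))
  cat(sprintf("  time_scale = %g", x$time_scale))
  if (!is.null(x$nominal_period))
    cat(sprintf(", nominal period = %g h", x$nominal_period))
  cat("\n")
  if (length(x$input_ports))
    cat("  input ports:", paste(sprintf("%s=%g", names(x$input_ports),
                                        x$input_ports), collapse = ", "), "\n")
  if (length(x$output_ports))
    cat("  output ports:", paste(sprintf("%s->%s", names(x$output_ports),
                                         x$output_ports), collapse = ", "), "\n")
  invisible(x)
}

#' Update a model parameter (or the time scale) in place
#'
#' @param model an `oscillator_model`.
#' @param name parameter name; `"time_scale"` addresses the time-scale factor.
#' @param value new numeric value.
#' @return the updated model.
#' @export
set_param <- function(model, name, value) {
  stopifnot(inherits(model, "oscillator_model"), is.numeric(value),
            length(value) == 1)
  if (identical(name, "time_scale")) {
    if (value <= 0) stop("time_scale must be positive")
    model$time_scale <- value
  } else {
    if (!name %in% names(model$params))
      stop("unknown parameter: ", name)
    model$params[[name]] <- value
  }
  model
}

## ---------------------------------------------------------------------------
## Radial-polynomial planar oscillators (the analytic oracle family)
## ---------------------------------------------------------------------------

## coefficients (ascending in u = r^2) of prod_i (u - rho_i^2)
radii_to_coefs <- function(radii) {
  coefs <- 1
  for (rho in radii) coefs <- c(0, coefs) - c(rho^2 * coefs, 0)
  coefs
}

radial_rhs <- function(t, y, params, ports) {
  coefs <- radial_coefs(params)
  u <- y[1]^2 + y[2]^2
  q <- sum(coefs * u^(seq_along(coefs) - 1))
  g <- -params[["k"]] * q
  w <- params[["omega0"]] + params[["beta"]] * u
  c(g * y[1] - w * y[2], g * y[2] + w * y[1])
}

## dispatch on which parameterization of Q the params carry
radial_coefs <- function(params) {
  if ("c" %in% names(params)) {
    cc <- params[["c"]]; mu <- params[["mu"]]
    ## (u - 1) * ((u - c)^2 - mu)
    c(-(cc^2 - mu), cc^2 - mu + 2 * cc, -(2 * cc + 1), 1)
  } else {
    radii_to_coefs(params[grep("^rho", names(params))])
  }
}

radial_compiled <- list(
  func = "multisync_radial_derivs",
  initfunc = "multisync_radial_init",
  parms = function(model, ports) {
    coefs <- radial_coefs(model$params)
    if (length(coefs) > 8) stop("radial polynomial degree too high for the compiled path")
    ts <- model$time_scale
    c(model$params[["k"]] / ts, model$params[["omega0"]] / ts,
      model$params[["beta"]] / ts, length(coefs),
      coefs, rep(0, 8 - length(coefs)))
  }
)

#' Multi-limit-cycle normal-form oscillator
#'
#' A planar system, written in Cartesian coordinates, whose radial part is
#' `dr/dt = -k r prod_i (r^2 - rho_i^2)` and whose angular part is
#' `dtheta/dt = omega0 + beta r^2`. With an odd number m of strictly
#' increasing radii, the circles at `rho_1, rho_3, ...` are stable limit
#' cycles and those at `rho_2, rho_4, ...` are unstable; the origin is an
#' unstable focus. The cycle at radius rho has period
#' `2*pi / (omega0 + beta * rho^2)` exactly, which makes this family the
#' analytic oracle for every downstream analysis: birhythmic (m = 3) and
#' trirhythmic (m = 5) configurations have exactly known attractors, basins
#' and periods.
#'
#' @param radii strictly increasing positive radii, odd count (max 7).
#' @param omega0 base angular velocity (rad/h).
#' @param shear amplitude-dependent angular shear beta (rad/h per unit r^2).
#' @param relax radial relaxation rate k (1/h per (units)^(2m)).
#' @return an `oscillator_model` with variables `x`, `y`.
#' @export
make_normal_form <- function(radii, omega0 = 2 * pi / 24, shear = 0,
                             relax = 1e-2) {
  m <- length(radii)
  if (m %% 2 == 0) stop("the number of radii must be odd")
  if (any(radii <= 0) || any(diff(radii) <= 0))
    stop("radii must be strictly increasing and positive")
  if (m > 7) stop("at most 7 radii are supported")
  if (omega0 <= 0) stop("omega0 must be positive")
  if (relax <= 0) stop("relax must be positive")
  params <- c(k = relax, omega0 = omega0, beta = shear)
  params[paste0("rho", seq_len(m))] <- radii
  oscillator_model(
    name = sprintf("normal_form_m%d", m),
    var_labels = c("x", "y"), params = params, rhs = radial_rhs,
    output_ports = c(readout = "x"),
    nominal_period = 2 * pi / (omega0 + shear * radii[1]^2),
    nonneg = FALSE, compiled = radial_compiled
  )
}

#' Closed-form attractor table of a normal-form oscillator
#'
#' @param model a model built by [make_normal_form()].
#' @return data.frame with radius, stability, and exact period of each
#'   invariant circle, ordered by radius.
#' @export
normal_form_attractors <- function(model) {
  radii <- unname(model$params[grep("^rho", names(model$params))])
  stable <- seq_along(radii) %% 2 == 1
  period <- model$time_scale * 2 * pi /
    (model$params[["omega0"]] + model$params[["beta"]] * radii^2)
  data.frame(radius = radii, stable = stable, period = period)
}

#' Predict the attractor reached from a given radius (sign analysis)
#'
#' Pure sign analysis of the radial flow: from radius r0 the trajectory
#' converges to the nearest stable radius not blocked by an unstable one.
#'
#' @param model a model built by [make_normal_form()].
#' @param r0 initial radius (> 0).
#' @return the stable radius reached.
#' @export
normal_form_basin_of <- function(model, r0) {
  att <- normal_form_attractors(model)
  stable <- att$radius[att$stable]
  unstable <- att$radius[!att$stable]
  ## basin boundaries are the unstable circles (and 0 below the first cycle)
  bounds <- c(0, unstable, Inf)
  idx <- findInterval(r0, bounds, left.open = TRUE)
  stable[idx]
}

#' Radial hysteresis fixture with a saddle-node of cycles
#'
#' Planar oscillator with radial polynomial
#' `dr/dt = -k r (r^2 - 1) ((r^2 - c)^2 - mu)`. For `mu` in (0, c^2) and
#' `c > 1 + sqrt(mu)` two stable limit cycles coexist, at r = 1 and at
#' `r = sqrt(c + sqrt(mu))`, separated by an unstable cycle at
#' `r = sqrt(c - sqrt(mu))`. The outer pair collides and disappears in a
#' saddle-node of cycles as `mu` crosses 0, which makes a back-and-forth
#' sweep of `mu` the closed-form oracle for hysteresis detection.
#'
#' @param c_center square of the radius around which the outer cycle pair
#'   collides (default 4: outer cycles near r = 2).
#' @param mu unfolding parameter of the saddle-node of cycles.
#' @param relax radial relaxation rate k.
#' @param omega0 angular velocity (rad/h).
#' @return an `oscillator_model` with parameters `c`, `mu`, `k`, `omega0`.
#' @export
make_ring_hysteresis <- function(c_center = 4, mu = 0.25, relax = 0.05,
                                 omega0 = 2 * pi / 24) {
  stopifnot(c_center > 1, relax > 0, omega0 > 0)
  oscillator_model(
    name = "ring_hysteresis",
    var_labels = c("x", "y"),
    params = c(k = relax, omega0 = omega0, beta = 0, c = c_center, mu = mu),
    rhs = radial_rhs,
    output_ports = c(readout = "x"),
    nominal_period = 2 * pi / omega0,
    nonneg = FALSE, compiled = radial_compiled
  )
}

## ---------------------------------------------------------------------------
## Clock-like negative-feedback oscillator
## ---------------------------------------------------------------------------

## Free-running period of the clock at time_scale = 1, measured once at
## rtol 1e-10 over a 6000 h run discarding 4000 h (see the methods vignette).
## The shipped time scale maps the free-running period to 24 h exactly up to
## integrator error, via the exact rescaling property.
GOODWIN_BASE_PERIOD <- 32.332342
GOODWIN_TAU <- 24 / GOODWIN_BASE_PERIOD

goodwin_rhs <- function(t, y, params, ports) {
  R <- ports[["R"]]
  M <- y[1]; P <- y[2]; I <- y[3]
  Kn <- params[["K1"]]^params[["n"]]
  In <- max(I, 0)^params[["n"]]
  c(params[["v1"]] * Kn / (Kn + In) * R -
      params[["v2"]] * M / (params[["K2"]] + M),
    params[["k3"]] * M - params[["v4"]] * P / (params[["K4"]] + P),
    params[["k5"]] * P - params[["v6"]] * I / (params[["K6"]] + I))
}

goodwin_param_order <- c("v1", "K1", "n", "v2", "K2", "k3", "v4", "K4",
                         "k5", "v6", "K6")

goodwin_compiled <- list(
  func = "multisync_goodwin_derivs",
  initfunc = "multisync_goodwin_init",
  parms = function(model, ports) {
    c(model$time_scale, unname(model$params[goodwin_param_order]),
      ports[["R"]])
  }
)

#' Clock-like negative-feedback (Goodwin-type) oscillator
#'
#' Three-variable transcriptional negative-feedback loop standing in for the
#' circadian limb: clock mRNA `M` is synthesized under Hill repression by the
#' nuclear repressor `I` and multiplied by the mitotic-repression input port
#' `R` (neutral default 1, i.e. no repression); cytosolic clock protein `P`
#' is translated from `M`; `I` is produced from `P`. All degradations are
#' Michaelian. The output port `clock_readout` exposes `P`, the BMAL1-proxy
#' that drives Wee1 induction under coupling. The default time scale is
#' calibrated so the free-running period is 24.0 h (within 0.1 h).
#'
#' @param time_scale time-scale factor tau dividing every rate; the default
#'   yields a 24 h free-running period.
#' @param check if TRUE, integrate the model and verify it oscillates with a
#'   period within 0.1 h of 24 h times `time_scale / GOODWIN_TAU`.
#' @return an `oscillator_model` with variables `M`, `P`, `I`.
#' @export
make_goodwin_clock <- function(time_scale = GOODWIN_TAU, check = FALSE) {
  if (!is.numeric(time_scale) || time_scale <= 0)
    stop("time_scale must be positive")
  model <- oscillator_model(
    name = "goodwin_clock",
    var_labels = c("M", "P", "I"),
    var_units = rep("µM", 3),
    params = c(v1 = 0.7, K1 = 1, n = 8, v2 = 0.35, K2 = 1,
               k3 = 0.7, v4 = 0.35, K4 = 1, k5 = 0.7, v6 = 0.35, K6 = 1),
    rhs = goodwin_rhs, time_scale = time_scale,
    input_ports = c(R = 1),
    output_ports = c(clock_readout = "P"),
    nominal_period = 24 * time_scale / GOODWIN_TAU,
    nonneg = TRUE, compiled = goodwin_compiled
  )
  if (check) check_oscillates(model, model$nominal_period, tol = 0.1,
                              variable = "P")
  model
}

#' Default initial state for the clock model
#' @return named numeric state vector.
#' @export
goodwin_init_state <- function() c(M = 0.1, P = 0.1, I = 0.1)

## ---------------------------------------------------------------------------
## Cell-cycle-like relaxation oscillator
## ---------------------------------------------------------------------------

## Free-running period at time_scale = 1 (same protocol as the clock).
CDK_BASE_PERIOD <- 26.044732
CDK_EPS_REF <- 19.1 / CDK_BASE_PERIOD

cdk_rhs <- function(t, y, params, ports) {
  S <- ports[["S"]]
  C <- y[1]; A <- y[2]; X <- y[3]; W <- y[4]
  ind <- if (params[["vsw"]] > 0 && S > 0) {
    Sh <- S^params[["hw"]]
    params[["vsw"]] * Sh / (params[["Kw"]]^params[["hw"]] + Sh)
  } else 0
  c(params[["vi"]] - params[["vd"]] * X * C / (params[["Kd"]] + C) -
      params[["kdeg"]] * C,
    params[["VM1"]] * (C / (params[["Kc"]] + C)) * (1 - A) /
      (params[["K1g"]] + 1 - A) -
      params[["V2"]] * (1 + params[["alpha"]] * W) * A / (params[["K2g"]] + A),
    params[["VM3"]] * A * (1 - X) / (params[["K3g"]] + 1 - X) -
      params[["V4"]] * X / (params[["K4g"]] + X),
    params[["ksw"]] + ind - params[["kdw"]] * W)
}

cdk_param_order <- c("vi", "vd", "Kd", "kdeg", "VM1", "Kc", "K1g",
                     "V2", "K2g", "alpha", "VM3", "K3g", "V4", "K4g",
                     "ksw", "kdw")

cdk_compiled <- list(
  func = "multisync_cdk_derivs",
  initfunc = "multisync_cdk_init",
  parms = function(model, ports) {
    c(model$time_scale, unname(model$params[cdk_param_order]),
      unname(model$params[c("vsw", "Kw", "hw")]), ports[["S"]])
  }
)

#' Cell-cycle-like relaxation oscillator with a Wee1 limb
#'
#' Four variables: cyclin `C` (synthesized at a constant rate, degraded at a
#' rate activated by `X`), Cdk1-like activity `A` (activated by cyclin via a
#' Michaelian step, inactivated at a rate increased by the Wee1-like kinase
#' `W`), degradation activator `X` (switched on by `A`), and `W` (basal
#' synthesis plus clock-driven induction `vsw * S^hw / (Kw^hw + S^hw)` where
#' `S` is the clock signal delivered on the input port, default 0 = coupling
#' off). Every rate is divided by the time-scale factor eps; the default eps
#' calibrates the free-running period to 19.1 h.
#'
#' The cyclin/Cdk1/APC core follows the classic minimal mitotic-oscillator
#' architecture (activation/inactivation cycles operating near saturation,
#' hence relaxation-type dynamics). Output port `cdk1_like` exposes `A`.
#'
#' @param eps time-scale factor; the default yields a 19.1 h period.
#' @param check if TRUE, verify oscillation and period at construction.
#' @return an `oscillator_model` with variables `C`, `A`, `X`, `W`.
#' @export
make_cdk_cycle <- function(eps = CDK_EPS_REF, check = FALSE) {
  if (!is.numeric(eps) || eps <= 0) stop("eps must be positive")
  model <- oscillator_model(
    name = "cdk_cycle",
    var_labels = c("C", "A", "X", "W"),
    var_units = c("µM", "fraction", "fraction", "µM"),
    params = c(vi = 0.025, vd = 0.25, Kd = 0.02, kdeg = 0.01,
               VM1 = 3, Kc = 0.5, K1g = 0.005,
               V2 = 1.5, K2g = 0.005, alpha = 0.3,
               VM3 = 1, K3g = 0.005, V4 = 0.5, K4g = 0.005,
               ksw = 0.115, kdw = 0.5,
               vsw = 0, Kw = 0.5, hw = 4),
    rhs = cdk_rhs, time_scale = eps,
    input_ports = c(S = 0),
    output_ports = c(cdk1_like = "A"),
    nominal_period = 19.1 * eps / CDK_EPS_REF,
    nonneg = TRUE, compiled = cdk_compiled
  )
  if (check) check_oscillates(model, model$nominal_period, tol = 0.2,
                              variable = "A")
  model
}

#' Default initial state for the cell-cycle model
#' @return named numeric state vector.
#' @export
cdk_init_state <- function() c(C = 0.1, A = 0.01, X = 0.01, W = 0.2)

## construction-time oscillation self-check shared by the stand-ins
check_oscillates <- function(model, expected_period, tol, variable) {
  cfg <- integrator_config(dt_out = 0.05)
  y0 <- if (model$name == "goodwin_clock") goodwin_init_state()
        else cdk_init_state()
  tr <- integrate_model(model, y0, 0, 30 * expected_period, cfg)
  pe <- tryCatch(estimate_period(tr, variable,
                                 discard = 20 * expected_period),
                 error = function(e) stop("oscillation self-check failed for '",
                                          model$name, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (abs(pe$period - expected_period) > tol)
    stop(sprintf("self-check: period %.3f h outside %g ± %g h",
                 pe$period, expected_period, tol), call. = FALSE)
  invisible(TRUE)
}

## ---------------------------------------------------------------------------
## Bidirectional coupling
## ---------------------------------------------------------------------------

#' Specify the bidirectional clock/cell-cycle coupling
#'
#' @param v_sw maximum clock-driven Wee1-induction rate (uM/h).
#' @param K_ICdk1 inhibition constant of the Cdk1-like repression of clock
#'   transcription (uM); smaller values mean stronger repression.
#' @param h_w Hill exponent of Wee1 induction (>= 1).
#' @param g_r Hill exponent of mitotic repression (>= 1).
#' @param K_w half-saturation constant of Wee1 induction by the clock
#'   signal (uM).
#' @param t_c coupling onset time (h); before `t_c` both oscillators run
#'   free, from `t_c` on the coupling terms are active.
#' @param clock_readout output-port name on the clock model feeding Wee1
#'   induction.
#' @param cycle_readout output-port name on the cell-cycle model feeding
#'   mitotic repression.
#' @return a `coupling_spec` object.
#' @export
coupling_spec <- function(v_sw, K_ICdk1, h_w = 4, g_r = 2, K_w = 0.5,
                          t_c = 0, clock_readout = "clock_readout",
                          cycle_readout = "cdk1_like") {
  if (v_sw < 0) stop("v_sw must be >= 0")
  if (K_ICdk1 <= 0) stop("K_ICdk1 must be positive")
  if (h_w < 1 || g_r < 1) stop("Hill exponents must be >= 1")
  structure(list(v_sw = v_sw, K_ICdk1 = K_ICdk1, h_w = h_w, g_r = g_r,
                 K_w = K_w, t_c = t_c, clock_readout = clock_readout,
                 cycle_readout = cycle_readout),
            class = "coupling_spec")
}

#' Mitotic-repression factor
#'
#' The multiplicative factor applied to clock mRNA synthesis under coupling:
#' `R = K_ICdk1^g_r / (K_ICdk1^g_r + A^g_r)` with `A` the Cdk1-like activity.
#' `R = 1` means no repression, `R = 1/2` at `A = K_ICdk1`.
#'
#' @param A Cdk1-like activity.
#' @param K_ICdk1 inhibition constant.
#' @param g_r Hill exponent.
#' @return repression factor in (0, 1].
#' @export
mitotic_repression <- function(A, K_ICdk1, g_r = 2) {
  Kg <- K_ICdk1^g_r
  Kg / (Kg + pmax(A, 0)^g_r)
}

#' Clock-driven Wee1 induction rate
#'
#' `v_sw * S^h_w / (K_w^h_w + S^h_w)` with `S` the clock readout.
#'
#' @param S clock signal (uM).
#' @param v_sw maximum induction rate (uM/h).
#' @param K_w half-saturation constant (uM).
#' @param h_w Hill exponent.
#' @return induction rate (uM/h).
#' @export
wee1_induction <- function(S, v_sw, K_w = 0.5, h_w = 4) {
  Sh <- pmax(S, 0)^h_w
  v_sw * Sh / (K_w^h_w + Sh)
}

#' Reference strong-coupling configuration
#'
#' The shipped coupling-strength setting at which the clock/cell-cycle pair
#' synchronizes 1:1 in a unique mode (mono-synchronization) for every
#' coupling onset time: strong Wee1 induction combined with strong mitotic
#' repression pulls the pair onto a single attractor. Used by the reference
#' onset-sweep protocol and the demo configs.
#'
#' @param t_c coupling onset time (h).
#' @return a [coupling_spec()].
#' @export
strong_coupling_spec <- function(t_c = 1000) {
  coupling_spec(v_sw = 2, K_ICdk1 = 0.5, h_w = 4, g_r = 2, K_w = 0.5,
                t_c = t_c)
}

coupled_compiled <- list(
  func = "multisync_coupled_derivs",
  initfunc = "multisync_coupled_init",
  parms = function(model, ports) {
    p <- model$params
    c(p[["tau_clock"]], unname(p[goodwin_param_order]),
      p[["eps_cycle"]], unname(p[cdk_param_order]),
      unname(p[c("vsw", "Kw", "hw", "K_I", "g_r", "coupled")]))
  }
)

#' Couple a clock model and a cell-cycle model bidirectionally
#'
#' Composes the two models into a single system whose state is the
#' concatenation of the two state vectors. Under active coupling
#' (`coupled = 1`): the cycle's Wee1 port receives the clock readout through
#' the `v_sw` Hill term, and the clock's repression port receives
#' `R = K_ICdk1^g_r / (K_ICdk1^g_r + A^g_r)` with `A` the Cdk1-like readout.
#' With `coupled = 0` (or `v_sw = 0` and `K_ICdk1 -> Inf`) the two systems
#' evolve exactly as when run separately.
#'
#' The composed parameter vector holds both submodels' parameters (their
#' names must not clash), the submodels' time scales as `tau_clock` and
#' `eps_cycle`, the coupling constants `vsw`, `Kw`, `hw`, `K_I`, `g_r`, and
#' the `coupled` switch. [integrate_with_onset()] toggles `coupled` at the
#' onset time `t_c` carried by the coupling spec.
#'
#' @param clock clock-side `oscillator_model` (input port `R`).
#' @param cycle cell-cycle-side `oscillator_model` (input port `S`).
#' @param coupling a [coupling_spec()].
#' @return an object of class `coupled_system` (also an `oscillator_model`).
#' @export
make_coupled <- function(clock, cycle, coupling) {
  stopifnot(inherits(clock, "oscillator_model"),
            inherits(cycle, "oscillator_model"),
            inherits(coupling, "coupling_spec"))
  if (!coupling$clock_readout %in% names(clock$output_ports))
    stop("clock model has no output port '", coupling$clock_readout, "'")
  if (!coupling$cycle_readout %in% names(cycle$output_ports))
    stop("cycle model has no output port '", coupling$cycle_readout, "'")
  if (!"R" %in% names(clock$input_ports))
    stop("clock model has no repression input port 'R'")
  if (!"S" %in% names(cycle$input_ports))
    stop("cycle model has no clock-signal input port 'S'")
  clash <- intersect(names(clock$params), names(cycle$params))
  if (length(clash))
    stop("parameter name clash between models: ", paste(clash, collapse = ", "))

  n_clock <- clock$n_vars
  i_clock <- seq_len(n_clock)
  i_cycle <- n_clock + seq_len(cycle$n_vars)
  s_var <- match(clock$output_ports[[coupling$clock_readout]],
                 clock$var_labels)
  a_var <- match(cycle$output_ports[[coupling$cycle_readout]],
                 cycle$var_labels)

  params <- c(clock$params, cycle$params,
              tau_clock = clock$time_scale, eps_cycle = cycle$time_scale,
              K_I = coupling$K_ICdk1, g_r = coupling$g_r, coupled = 1)
  ## coupling overrides the cycle's induction machinery
  params[["vsw"]] <- coupling$v_sw
  params[["Kw"]] <- coupling$K_w
  params[["hw"]] <- coupling$h_w

  clock_rhs <- clock$rhs
  cycle_rhs <- cycle$rhs
  rhs <- function(t, y, params, ports) {
    if (params[["coupled"]] > 0) {
      S <- y[i_clock][s_var]
      R <- mitotic_repression(y[i_cycle][a_var], params[["K_I"]],
                              params[["g_r"]])
      vsw_eff <- params[["vsw"]]
    } else {
      S <- 0; R <- 1; vsw_eff <- 0
    }
    pc <- params; pc[["vsw"]] <- vsw_eff
    c(clock_rhs(t, y[i_clock], params, list(R = R)) / params[["tau_clock"]],
      cycle_rhs(t, y[i_cycle], pc, list(S = S)) / params[["eps_cycle"]])
  }

  compiled <- if (identical(clock$compiled, goodwin_compiled) &&
                  identical(cycle$compiled, cdk_compiled)) coupled_compiled

  model <- oscillator_model(
    name = sprintf("coupled_%s_%s", clock$name, cycle$name),
    var_labels = c(clock$var_labels, cycle$var_labels),
    var_units = c(clock$var_units, cycle$var_units),
    params = params, rhs = rhs, time_scale = 1,
    output_ports = c(clock$output_ports, cycle$output_ports),
    nonneg = c(clock$nonneg, cycle$nonneg),
    compiled = compiled
  )
  model$clock <- clock
  model$cycle <- cycle
  model$coupling <- coupling
  model$i_clock <- i_clock
  model$i_cycle <- i_cycle
  class(model) <- c("coupled_system", class(model))
  model
}

## composed rhs divides by each submodel's own time scale internally, so the
## generic engine-side division must see time_scale 1; guard against misuse
#' @export
print.coupled_system <- function(x, ...) {
  cat(sprintf("<coupled_system> %s (+) %s\n", x$clock$name, x$cycle$name))
  cat(sprintf("  v_sw = %g µM/h, K_ICdk1 = %g µM, h_w = %g, g_r = %g, t_c = %g h\n",
              x$coupling$v_sw, x$coupling$K_ICdk1, x$coupling$h_w,
              x$coupling$g_r, x$coupling$t_c))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Periodic forcing
## ---------------------------------------------------------------------------

#' Specify periodic forcing of a model parameter
#'
#' @param target name of the forced parameter.
#' @param kind `"square"` or `"sinusoid"`.
#' @param period forcing period (h).
#' @param amplitude square: half peak-to-trough excursion (parameter units);
#'   sinusoid: relative amplitude, `p(t) = p0 (1 + amplitude sin(2 pi t/T))`.
#' @param duty fraction of the cycle spent at the high level (square only).
#' @param clip if TRUE, a sinusoid that would drive the parameter negative is
#'   clipped at 0; if FALSE that is a validation error.
#' @return a `forcing_spec` object.
#' @export
forcing_spec <- function(target, kind = c("sinusoid", "square"),
                         period, amplitude, duty = 0.5, clip = TRUE) {
  kind <- match.arg(kind)
  if (period <= 0) stop("forcing period must be positive")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (kind == "square" && (duty <= 0 || duty >= 1))
    stop("duty must be in (0, 1)")
  structure(list(target = target, kind = kind, period = period,
                 amplitude = amplitude, duty = duty, clip = clip),
            class = "forcing_spec")
}

#' Evaluate the forcing waveform
#'
#' The time course of the forced parameter. For a square wave with baseline
#' p0, amplitude a, and duty d the high/low levels are `p0 + a (1 - d)` and
#' `p0 - a d`, so the cycle mean is preserved at p0.
#'
#' @param forcing a [forcing_spec()].
#' @param p0 baseline parameter value.
#' @param t time(s) (h).
#' @return forced parameter value(s) at `t`.
#' @export
forcing_value <- function(forcing, p0, t) {
  if (forcing$kind == "square") {
    hi <- p0 + forcing$amplitude * (1 - forcing$duty)
    lo <- p0 - forcing$amplitude * forcing$duty
    ph <- (t / forcing$period) %% 1
    ifelse(ph < forcing$duty, hi, lo)
  } else {
    v <- p0 * (1 + forcing$amplitude * sin(2 * pi * t / forcing$period))
    pmax(v, 0)
  }
}

#' Force a model parameter periodically in time
#'
#' Returns a non-autonomous variant of `model` whose `target` parameter
#' follows [forcing_value()]. For the shipped clock model forced on its mRNA
#' synthesis rate `v1` a compiled right-hand side is used; any other
#' model/parameter combination runs through the generic R path.
#'
#' @param model an `oscillator_model`.
#' @param forcing a [forcing_spec()].
#' @return an `oscillator_model` (non-autonomous).
#' @export
make_forced <- function(model, forcing) {
  stopifnot(inherits(model, "oscillator_model"),
            inherits(forcing, "forcing_spec"))
  if (!forcing$target %in% names(model$params))
    stop("model has no parameter '", forcing$target, "'")
  p0 <- model$params[[forcing$target]]
  if (forcing$kind == "square" && p0 - forcing$amplitude * forcing$duty < 0)
    stop("square forcing drives '", forcing$target, "' negative")
  if (forcing$kind == "sinusoid" && forcing$amplitude > 1 && !forcing$clip)
    stop("sinusoidal forcing would drive '", forcing$target,
         "' negative and clipping is disabled")

  base_rhs <- model$rhs
  target <- forcing$target
  forced <- model
  forced$name <- paste0(model$name, "_forced")
  forced$forcing <- forcing
  forced$rhs <- function(t, y, params, ports) {
    params[[target]] <- forcing_value(forcing, p0, t)
    base_rhs(t, y, params, ports)
  }
  forced$compiled <- NULL
  if (identical(model$compiled, goodwin_compiled) && target == "v1") {
    kind_code <- if (forcing$kind == "square") 1 else 2
    hi <- p0 + forcing$amplitude * (1 - forcing$duty)
    lo <- p0 - forcing$amplitude * forcing$duty
    forced$compiled <- list(
      func = "multisync_goodwin_forced_derivs",
      initfunc = "multisync_goodwin_forced_init",
      parms = function(model, ports) {
        c(model$time_scale, unname(model$params[goodwin_param_order]),
          ports[["R"]], kind_code, forcing$period, forcing$amplitude,
          forcing$duty, lo, hi)
      }
    )
  }
  forced
}

## ---------------------------------------------------------------------------
## Manifests
## ---------------------------------------------------------------------------

#' Serializable manifest record of a model
#'
#' @param model an `oscillator_model`.
#' @return a plain list (name, variables, parameters, ports, time scale,
#'   tuned constants) suitable for [yaml::write_yaml()].
#' @export
model_manifest <- function(model) {
  m <- list(
    name = model$name,
    n_vars = model$n_vars,
    var_labels = as.list(stats::setNames(model$var_units, model$var_labels)),
    params = as.list(model$params),
    time_scale = model$time_scale,
    input_ports = as.list(model$input_ports),
    output_ports = as.list(model$output_ports)
  )
  if (!is.null(model$nominal_period)) m$nominal_period <- model$nominal_period
  if (inherits(model, "coupled_system"))
    m$coupling <- unclass(model$coupling)
  if (!is.null(model$forcing)) m$forcing <- unclass(model$forcing)
  m
}
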