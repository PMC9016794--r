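## ---------------------------------------------------------------------------
## Mode clustering and census containers
## ---------------------------------------------------------------------------

#' Cluster attractor fingerprints into distinct modes
#'
#' Single-linkage agglomeration under [attractor_distance()]: two
#' fingerprints land in the same cluster when they are connected by a chain
#' of pairwise distances not exceeding `threshold` (ties at the threshold
#' merge, so mode counting is conservative). The cluster representative is
#' the member with the median period; clusters are ordered by ascending
#' representative period (steady-state clusters last). The result is
#' deterministic under permutation of the input.
#'
#' @param fps non-empty list of `attractor_fingerprint`s over one variable
#'   set.
#' @param threshold clustering distance threshold.
#' @return a `mode_clusters` object: `assignment` (integer per input),
#'   `representatives` (list of fingerprints), `sizes`.
#' @export
cluster_modes <- function(fps, threshold = 0.01) {
  n <- length(fps)
  if (n == 0) stop("no fingerprints to cluster")
  ## union-find over the graph with edges d <= threshold (single linkage)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      ## already connected pairs need no distance evaluation
      ri <- find(i); rj <- find(j)
      if (ri == rj) next
      d <- attractor_distance(fps[[i]], fps[[j]])
      if (is.finite(d) && d <= threshold)
        parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- match(roots, sort(unique(roots)))
  k <- max(ids)
  reps <- vector("list", k)
  rep_period <- numeric(k)
  for (g in seq_len(k)) {
    members <- which(ids == g)
    periods <- vapply(fps[members], function(f) f$period, numeric(1))
    if (all(is.na(periods))) {
      reps[[g]] <- fps[[members[1]]]
      rep_period[g] <- NA_real_
    } else {
      ## member with the median period, lower median for even counts
      ord <- members[order(periods)]
      reps[[g]] <- fps[[ord[ceiling(length(ord) / 2)]]]
      rep_period[g] <- reps[[g]]$period
    }
  }
  ## order clusters by ascending representative period (amplitude breaks
  ## period ties), steady states last
  rep_amp <- vapply(reps, function(f) mean(f$amplitude), numeric(1))
  ord <- order(is.na(rep_period), round(rep_period, 2), rep_amp)
  relabel <- match(seq_len(k), ord)
  structure(list(assignment = relabel[ids],
                 representatives = reps[ord],
                 sizes = as.integer(table(factor(relabel[ids],
                                                 levels = seq_len(k)))),
                 threshold = threshold),
            class = "mode_clusters")
}

mode_classification <- function(n_modes) {
  if (n_modes == 0) "none"
  else if (n_modes == 1) "mono"
  else if (n_modes == 2) "bi"
  else if (n_modes == 3) "tri"
  else "higher"
}

new_mode_census <- function(assignment_table, clusters, threshold, meta) {
  n_modes <- if (is.null(clusters)) 0L else length(clusters$representatives)
  synced <- assignment_table$mode > 0 & !is.na(assignment_table$mode)
  counts <- if (n_modes > 0)
    as.integer(table(factor(assignment_table$mode[synced],
                            levels = seq_len(n_modes))))
  else integer(0)
  basin <- if (sum(counts) > 0) counts / sum(counts) else numeric(0)
  structure(list(
    modes = if (is.null(clusters)) list() else clusters$representatives,
    counts = counts,
    basin_fraction = basin,
    assignment = assignment_table,
    classification = mode_classification(n_modes),
    n_failed = sum(assignment_table$status == "failed"),
    threshold = threshold,
    meta = meta
  ), class = "mode_census")
}

#' @export
print.mode_census <- function(x, ...) {
  cat(sprintf("<mode_census> %d runs, classification '%s'\n",
              nrow(x$assignment), x$classification))
  if (length(x$modes)) {
    for (g in seq_along(x$modes)) {
      cat(sprintf("  mode %d: period %.2f h, %d runs (basin fraction %.3f)\n",
                  g, x$modes[[g]]$period, x$counts[g], x$basin_fraction[g]))
    }
  }
  other <- table(x$assignment$status[x$assignment$mode == 0 |
                                       is.na(x$assignment$mode)])
  if (length(other))
    cat("  unsynchronized:",
        paste(sprintf("%s=%d", names(other), other), collapse = ", "), "\n")
  invisible(x)
}

#' Periods of the census modes
#' @param census a `mode_census`.
#' @return numeric vector of representative periods (h), ascending.
#' @export
mode_periods <- function(census) {
  vapply(census$modes, function(f) f$period, numeric(1))
}

## classify + fingerprint one settled trajectory; returns a status record
analyse_run <- function(traj, discard, variable, W) {
  regime <- classify_regime(traj, variable = variable, discard = discard)
  fp <- if (regime == "periodic")
    fingerprint(traj, discard = discard, variable = variable, W = W,
                regime = regime)
  list(regime = regime, fp = fp)
}

## ---------------------------------------------------------------------------
## Coupling-onset sweep (basin sampling via onset time)
## ---------------------------------------------------------------------------

#' Census the synchronization modes by sweeping the coupling onset time
#'
#' The basin-sampling protocol: the two oscillators run free from `t0`; the
#' bidirectional coupling is switched on at an onset time `t_c` swept over
#' an inclusive grid (default 1000 to 1030 h in steps of 0.05 h, 601 runs).
#' Because the free-running pair traverses its torus of relative phases,
#' each onset time hands the coupled system a different initial condition;
#' the attractor it settles on is fingerprinted and sync-checked, and the
#' fingerprints are clustered into distinct synchronization modes. The
#' per-onset assignment table is the machine-readable twin of a per-onset
#' mode bar chart.
#'
#' The free-running segment is integrated once and reused across onset
#' times, which is exact because the system is autonomous before onset.
#'
#' @param system a `coupled_system`.
#' @param t_c_start,t_c_end,dt_c onset-time grid (h).
#' @param post_discard transient to discard after onset (h; default 40
#'   putative cycles of the slower free period).
#' @param post_window analysis window after the transient (h).
#' @param cfg an [integrator_config()].
#' @param threshold mode-clustering distance threshold.
#' @param W waveform grid size.
#' @param tol_sync locking tolerance for [check_sync()].
#' @param y0_clock,y0_cycle free-running initial states.
#' @param t0 start of the free-running segment (h).
#' @param progress print one character per run.
#' @return a `mode_census`.
#' @export
onset_sweep <- function(system, t_c_start = 1000, t_c_end = 1030,
                        dt_c = 0.05, post_discard = NULL, post_window = NULL,
                        cfg = integrator_config(), threshold = 0.01,
                        W = 256, tol_sync = 1e-2,
                        y0_clock = goodwin_init_state(),
                        y0_cycle = cdk_init_state(),
                        t0 = 0, progress = FALSE) {
  stopifnot(inherits(system, "coupled_system"))
  if (dt_c <= 0 || t_c_end < t_c_start) stop("invalid onset grid")
  n_on <- floor((t_c_end - t_c_start) / dt_c + 1e-9)
  onsets <- t_c_start + dt_c * (0:n_on)
  free_T <- max(system$clock$nominal_period %||% 24,
                system$cycle$nominal_period %||% 24)
  if (is.null(post_discard)) post_discard <- 40 * free_T
  if (is.null(post_window)) post_window <- 15 * free_T

  ## one free-running integration, sampled exactly at the onset times
  free <- set_param(system, "coupled", 0)
  y0 <- c(y0_clock, y0_cycle)
  pre_times <- unique(c(t0, onsets))
  pre_state <- solve_ode(free, y0, pre_times, cfg, list())
  ic_at <- pre_state[match(onsets, pre_times), , drop = FALSE]

  var_A <- system$clock$output_ports[[system$coupling$clock_readout]]
  var_B <- system$cycle$output_ports[[system$coupling$cycle_readout]]
  on <- set_param(system, "coupled", 1)

  run_one <- function(i) {
    t_c <- onsets[i]
    times <- uniform_times(t_c, t_c + post_discard + post_window, cfg$dt_out)
    st <- tryCatch(solve_ode(on, ic_at[i, ], times, cfg, list()),
                   error = function(e) NULL)
    if (is.null(st))
      return(list(status = "failed", fp = NULL, period = NA_real_,
                  locked = FALSE, p = NA_integer_, q = NA_integer_))
    tr <- new_trajectory(times, st, system$var_labels, list())
    tr$provenance$model$output_ports <- as.list(system$output_ports)
    sync <- check_sync(tr, var_A, var_B, discard = post_discard,
                       tol_sync = tol_sync)
    regime <- tryCatch(
      classify_regime(tr, variable = var_B, discard = post_discard),
      error = function(e) "failed")
    if (sync$locked && regime == "periodic") {
      fp <- fingerprint(tr, discard = post_discard, variable = var_B, W = W,
                        regime = regime)
      list(status = "locked", fp = fp, period = sync$common_period,
           locked = TRUE, p = sync$p, q = sync$q)
    } else {
      ## individually periodic but unlocked = quasiperiodic composite
      lab <- if (regime == "periodic") "unsynchronized" else regime
      list(status = lab, fp = NULL, period = NA_real_,
           locked = FALSE, p = NA_integer_, q = NA_integer_)
    }
  }

  runs <- vector("list", length(onsets))
  for (i in seq_along(onsets)) {
    runs[[i]] <- run_one(i)
    if (progress) cat(if (runs[[i]]$locked) "." else "x")
  }
  if (progress) cat("\n")

  locked_idx <- which(vapply(runs, function(r) r$locked, logical(1)))
  clusters <- if (length(locked_idx))
    cluster_modes(lapply(runs[locked_idx], `[[`, "fp"), threshold)
  mode_of <- integer(length(onsets))
  if (length(locked_idx)) mode_of[locked_idx] <- clusters$assignment
  tab <- data.frame(
    t_c = onsets,
    status = vapply(runs, `[[`, character(1), "status"),
    mode = mode_of,
    period = vapply(runs, `[[`, numeric(1), "period"),
    locked = vapply(runs, `[[`, logical(1), "locked"),
    p = vapply(runs, `[[`, integer(1), "p"),
    q = vapply(runs, `[[`, integer(1), "q")
  )
  tab$status[tab$locked] <- paste0("M", tab$mode[tab$locked])
  new_mode_census(tab, clusters, threshold,
                  meta = list(system = model_manifest(system),
                              t_c_start = t_c_start, t_c_end = t_c_end,
                              dt_c = dt_c, post_discard = post_discard,
                              post_window = post_window,
                              tol_sync = tol_sync, cfg = unclass(cfg)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## Initial-condition census (single oscillator; analytic oracle protocol)
## ---------------------------------------------------------------------------

#' Census the coexisting attractors of one oscillator over initial states
#'
#' Runs the model from each initial state, classifies the settled regime,
#' fingerprints periodic runs and clusters them into distinct modes. This is
#' the protocol used against the analytic normal-form oracle, whose basins
#' and periods are known in closed form.
#'
#' @param model an `oscillator_model`.
#' @param y0_list list (or matrix, one row per run) of initial states.
#' @param t_end integration end time per run (h).
#' @param discard transient window (h).
#' @param cfg an [integrator_config()].
#' @param threshold clustering threshold.
#' @param variable reference variable (default: first output port).
#' @param W waveform grid size.
#' @return a `mode_census`; the assignment table carries one row per initial
#'   state.
#' @export
mode_census_ic <- function(model, y0_list, t_end, discard = NULL,
                           cfg = integrator_config(), threshold = 0.01,
                           variable = NULL, W = 256) {
  if (is.matrix(y0_list))
    y0_list <- lapply(seq_len(nrow(y0_list)), function(i) y0_list[i, ])
  if (!length(y0_list)) stop("no initial states")
  if (is.null(discard)) discard <- 0.6 * t_end
  runs <- lapply(y0_list, function(y0) {
    tr <- tryCatch(integrate_model(model, y0, 0, t_end, cfg),
                   error = function(e) NULL)
    if (is.null(tr)) return(list(status = "failed", fp = NULL,
                                 period = NA_real_))
    a <- tryCatch(
      analyse_run(tr, discard, variable %||% reference_variable(tr), W),
      error = function(e) list(regime = "failed", fp = NULL))
    if (a$regime == "periodic")
      list(status = "locked", fp = a$fp, period = a$fp$period)
    else list(status = a$regime, fp = NULL, period = NA_real_)
  })
  ok <- which(vapply(runs, function(r) !is.null(r$fp), logical(1)))
  clusters <- if (length(ok))
    cluster_modes(lapply(runs[ok], `[[`, "fp"), threshold)
  mode_of <- integer(length(runs))
  if (length(ok)) mode_of[ok] <- clusters$assignment
  tab <- data.frame(
    run = seq_along(runs),
    status = vapply(runs, `[[`, character(1), "status"),
    mode = mode_of,
    period = vapply(runs, `[[`, numeric(1), "period"),
    locked = mode_of > 0,
    p = NA_integer_, q = NA_integer_
  )
  tab$status[tab$locked] <- paste0("M", tab$mode[tab$locked])
  new_mode_census(tab, clusters, threshold,
                  meta = list(model = model_manifest(model), t_end = t_end,
                              discard = discard, cfg = unclass(cfg)))
}

## ---------------------------------------------------------------------------
## Two-parameter synchronization diagram
## ---------------------------------------------------------------------------

#' Mono/bi/tri-synchronization diagram over coupling strengths
#'
#' For each cell of a (v_sw, K_ICdk1) grid, runs an onset-time sweep (a
#' coarser onset grid than the reference protocol, by default 31 points over
#' the same 30 h span) and stores the mode census. Mode identity across
#' cells is established by re-clustering all cell representatives jointly,
#' so the per-mode period surfaces are globally consistent.
#'
#' @param clock,cycle the two submodels.
#' @param v_sw_grid,K_ICdk1_grid strictly increasing parameter grids.
#' @param n_onset onset grid points per cell.
#' @param t_c_start,t_c_span onset window (h).
#' @param coupling_defaults a [coupling_spec()] supplying h_w, g_r, K_w.
#' @param threshold clustering threshold.
#' @param cfg an [integrator_config()].
#' @param ... passed to [onset_sweep()] (e.g. `post_discard`).
#' @param progress print one line per cell.
#' @return a `sync_diagram`: `cells` data.frame (one row per cell:
#'   `v_sw`, `K_ICdk1`, `n_modes`, `classification`, `periods`,
#'   `global_modes`), `censuses` list, `mode_table` with the global mode
#'   ids, and `surfaces` (long-format period surface table keyed by cell
#'   and global mode).
#' @export
synchronization_diagram <- function(clock, cycle, v_sw_grid, K_ICdk1_grid,
                                    n_onset = 31, t_c_start = 1000,
                                    t_c_span = 30,
                                    coupling_defaults = coupling_spec(1, 1),
                                    threshold = 0.01,
                                    cfg = integrator_config(), ...,
                                    progress = FALSE) {
  if (any(diff(v_sw_grid) <= 0) || any(diff(K_ICdk1_grid) <= 0))
    stop("parameter grids must be strictly increasing")
  if (any(K_ICdk1_grid <= 0)) stop("K_ICdk1 must be positive")
  grid <- expand.grid(v_sw = v_sw_grid, K_ICdk1 = K_ICdk1_grid,
                      KEEP.OUT.ATTRS = FALSE)
  dt_c <- t_c_span / (n_onset - 1)
  censuses <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cs <- coupling_spec(v_sw = grid$v_sw[i], K_ICdk1 = grid$K_ICdk1[i],
                        h_w = coupling_defaults$h_w,
                        g_r = coupling_defaults$g_r,
                        K_w = coupling_defaults$K_w)
    system <- make_coupled(clock, cycle, cs)
    censuses[[i]] <- tryCatch(
      onset_sweep(system, t_c_start, t_c_start + t_c_span, dt_c,
                  cfg = cfg, threshold = threshold, ...),
      error = function(e) e)
    if (progress) {
      lab <- if (inherits(censuses[[i]], "error")) "failed"
             else censuses[[i]]$classification
      cat(sprintf("v_sw=%g K_ICdk1=%g -> %s\n",
                  grid$v_sw[i], grid$K_ICdk1[i], lab))
    }
  }
  ok <- !vapply(censuses, inherits, logical(1), "error")
  ## joint re-clustering of all cell representatives -> global mode ids
  all_reps <- list(); rep_cell <- integer(0); rep_local <- integer(0)
  for (i in which(ok)) {
    m <- censuses[[i]]$modes
    if (length(m)) {
      all_reps <- c(all_reps, m)
      rep_cell <- c(rep_cell, rep(i, length(m)))
      rep_local <- c(rep_local, seq_along(m))
    }
  }
  global <- if (length(all_reps)) cluster_modes(all_reps, threshold)
  surfaces <- NULL
  global_of_cell <- rep(list(integer(0)), nrow(grid))
  if (!is.null(global)) {
    for (j in seq_along(all_reps)) {
      i <- rep_cell[j]
      global_of_cell[[i]] <- c(global_of_cell[[i]], global$assignment[j])
    }
    surfaces <- data.frame(
      v_sw = grid$v_sw[rep_cell],
      K_ICdk1 = grid$K_ICdk1[rep_cell],
      global_mode = global$assignment,
      period = vapply(all_reps, function(f) f$period, numeric(1))
    )
  }
  cells <- data.frame(
    v_sw = grid$v_sw, K_ICdk1 = grid$K_ICdk1,
    n_modes = vapply(seq_len(nrow(grid)), function(i)
      if (ok[i]) length(censuses[[i]]$modes) else NA_integer_, integer(1)),
    classification = vapply(seq_len(nrow(grid)), function(i)
      if (ok[i]) censuses[[i]]$classification else "failed", character(1)),
    periods = vapply(seq_len(nrow(grid)), function(i)
      if (ok[i]) paste(sprintf("%.2f", mode_periods(censuses[[i]])),
                       collapse = ";") else "", character(1)),
    global_modes = vapply(global_of_cell, paste, character(1), collapse = ";")
  )
  structure(list(cells = cells, censuses = censuses,
                 v_sw_grid = v_sw_grid, K_ICdk1_grid = K_ICdk1_grid,
                 mode_table = if (is.null(global)) NULL else
                   data.frame(global_mode = seq_along(global$representatives),
                              period = vapply(global$representatives,
                                              function(f) f$period,
                                              numeric(1))),
                 surfaces = surfaces, threshold = threshold),
            class = "sync_diagram")
}

#' @export
print.sync_diagram <- function(x, ...) {
  cat(sprintf("<sync_diagram> %d x %d cells\n", length(x$v_sw_grid),
              length(x$K_ICdk1_grid)))
  print(x$cells)
  invisible(x)
}

## ---------------------------------------------------------------------------
## Hysteresis sweep
## ---------------------------------------------------------------------------

#' Back-and-forth parameter sweep with state carry-over
#'
#' Ramps a parameter stepwise from `lo` to `hi` and back, using each step's
#' final state as the next step's initial state, fingerprinting the settled
#' regime at every step. Loss of oscillation is recorded as a steady-state
#' fingerprint, not an error. The disagreement window -- grid points where
#' the forward- and backward-branch fingerprints differ beyond the cluster
#' threshold -- is the evidence for coexisting attractors (hysteresis).
#'
#' The backward branch starts from the forward branch's final state by
#' default; supply `y0_backward` to start it on a different attractor (e.g.
#' an outer cycle known to exist at `hi`).
#'
#' @param model an `oscillator_model`.
#' @param parameter parameter name to ramp (may be `"time_scale"`).
#' @param lo,hi sweep bounds.
#' @param n_steps number of grid points (>= 3).
#' @param settle integration time per step (h).
#' @param y0 initial state at `lo` for the forward branch.
#' @param y0_backward optional initial state at `hi` for the backward branch.
#' @param cfg an [integrator_config()].
#' @param threshold disagreement threshold on [attractor_distance()].
#' @param window analysis window at the end of each settle period (h).
#' @param variable reference variable.
#' @param W waveform grid size.
#' @return a `hysteresis_result`: `grid`, lists `forward` / `backward` of
#'   fingerprints, `distance` per grid point, logical `disagree`, and the
#'   `disagreement_window` (range of disagreeing grid values, or NULL).
#' @export
hysteresis_sweep <- function(model, parameter, lo, hi, n_steps, settle,
                             y0, y0_backward = NULL,
                             cfg = integrator_config(), threshold = 0.01,
                             window = NULL, variable = NULL, W = 256) {
  if (n_steps < 3) stop("n_steps must be >= 3")
  grid <- seq(lo, hi, length.out = n_steps)
  if (is.null(window)) window <- settle / 2
  sweep_branch <- function(values, y_start) {
    y <- y_start
    fps <- vector("list", length(values))
    for (i in seq_along(values)) {
      m <- set_param(model, parameter, values[i])
      tr <- integrate_model(m, y, 0, settle, cfg)
      y <- tr$state[nrow(tr$state), ]
      v <- variable %||% reference_variable(tr)
      regime <- tryCatch(
        classify_regime(tr, variable = v, discard = settle - window),
        error = function(e) "steady_state")
      fps[[i]] <- if (regime == "periodic")
        fingerprint(tr, discard = settle - window, variable = v, W = W,
                    regime = regime)
      else steady_fingerprint(stats::setNames(y, model$var_labels), W = W)
    }
    list(fps = fps, y_end = y)
  }
  fwd <- sweep_branch(grid, y0)
  back_start <- y0_backward %||% fwd$y_end
  bwd <- sweep_branch(rev(grid), back_start)
  bwd_fps <- rev(bwd$fps)
  d <- vapply(seq_along(grid), function(i) {
    di <- attractor_distance(fwd$fps[[i]], bwd_fps[[i]])
    if (is.infinite(di)) 1e6 else di
  }, numeric(1))
  disagree <- d > threshold
  win <- if (any(disagree)) range(grid[disagree])
  structure(list(parameter = parameter, grid = grid,
                 forward = fwd$fps, backward = bwd_fps,
                 distance = d, disagree = disagree,
                 disagreement_window = win, threshold = threshold),
            class = "hysteresis_result")
}

#' @export
print.hysteresis_result <- function(x, ...) {
  cat(sprintf("<hysteresis_result> '%s' over [%g, %g], %d steps\n",
              x$parameter, min(x$grid), max(x$grid), length(x$grid)))
  if (is.null(x$disagreement_window)) {
    cat("  no disagreement between branches (single attractor throughout)\n")
  } else {
    cat(sprintf("  branches disagree on [%g, %g] (%d grid points)\n",
                x$disagreement_window[1], x$disagreement_window[2],
                sum(x$disagree)))
  }
  invisible(x)
}

## ---------------------------------------------------------------------------
## Arnold-tongue entrainment map
## ---------------------------------------------------------------------------

#' Map p:q entrainment of a periodically forced oscillator
#'
#' For each cell of a (forcing period, amplitude) grid the forced model is
#' run from `n_phases` initial states spread over the free-running cycle,
#' and each run's verdict is the p:q locking of the response to the forcing
#' (p:q = forcing:response frequency ratio; unlocked when the settled regime
#' is not simple periodic or no small-integer ratio fits). Cells whose
#' verdict differs across starting phases flag the coexistence of
#' entrainment modes -- the overlap of Arnold tongues.
#'
#' @param model an autonomous `oscillator_model` with a free-running cycle.
#' @param target forced parameter name.
#' @param period_grid forcing periods (h), strictly increasing.
#' @param amplitude_grid forcing amplitudes (see [forcing_spec()]),
#'   non-negative, typically starting at 0 as a null row.
#' @param n_phases initial phases per cell (>= 1).
#' @param kind waveform kind.
#' @param y0 initial state used to settle onto the free-running cycle.
#' @param t_settle time to settle the free cycle (h).
#' @param t_end integration time per forced run (h).
#' @param discard transient discarded before the verdict (h).
#' @param tol_sync locking tolerance.
#' @param max_ratio largest p or q.
#' @param cfg an [integrator_config()].
#' @param progress print one line per amplitude row.
#' @return an `entrainment_map`: `cells` data.frame with one row per
#'   (period, amplitude, phase) run plus per-cell `locked`, `p`, `q`,
#'   `coexistence` summary table.
#' @export
arnold_map <- function(model, target, period_grid, amplitude_grid,
                       n_phases = 2, kind = "sinusoid",
                       y0, t_settle = 600, t_end = 900, discard = 600,
                       tol_sync = 1e-2, max_ratio = 4,
                       cfg = integrator_config(), progress = FALSE) {
  if (any(diff(period_grid) <= 0)) stop("period grid must be increasing")
  if (any(amplitude_grid < 0)) stop("amplitudes must be >= 0")
  if (n_phases < 1) stop("n_phases must be >= 1")
  ## settle onto the free-running cycle, then sample n_phases states
  free <- integrate_model(model, y0, 0, t_settle, cfg)
  v <- reference_variable(free)
  fp0 <- fingerprint(free, discard = t_settle * 0.6, variable = v)
  T0 <- fp0$period
  tail_t <- free$times[free$times >= t_settle - T0 - cfg$dt_out]
  phase_times <- tail_t[1] + T0 * (seq_len(n_phases) - 1) / n_phases
  states <- t(sapply(phase_times, function(tt)
    free$state[which.min(abs(free$times - tt)), ]))

  rows <- list()
  for (amp in amplitude_grid) {
    for (Tf in period_grid) {
      for (ph in seq_len(n_phases)) {
        forced <- make_forced(model, forcing_spec(target, kind = kind,
                                                  period = Tf,
                                                  amplitude = amp))
        res <- tryCatch({
          tr <- integrate_model(forced, states[ph, ], 0, t_end, cfg)
          regime <- classify_regime(tr, variable = v, discard = discard)
          if (regime == "periodic") {
            Tr <- estimate_period(tr, v, discard = discard)$period
            best <- NULL
            for (p in 1:max_ratio) for (q in 1:max_ratio) {
              if (gcd(p, q) != 1) next
              err <- abs(p * Tf - q * Tr) / (q * Tr)
              if (err < tol_sync && (is.null(best) || err < best$err))
                best <- list(p = p, q = q, err = err)
            }
            if (!is.null(best))
              list(locked = TRUE, p = best$p, q = best$q, period = Tr,
                   regime = regime)
            else list(locked = FALSE, p = NA_integer_, q = NA_integer_,
                      period = Tr, regime = regime)
          } else list(locked = FALSE, p = NA_integer_, q = NA_integer_,
                      period = NA_real_, regime = regime)
        }, error = function(e) list(locked = FALSE, p = NA_integer_,
                                    q = NA_integer_, period = NA_real_,
                                    regime = "failed"))
        rows[[length(rows) + 1]] <- data.frame(
          forcing_period = Tf, amplitude = amp, phase = ph,
          locked = res$locked, p = res$p, q = res$q,
          response_period = res$period, regime = res$regime)
      }
    }
    if (progress) cat(sprintf("amplitude %g done\n", amp))
  }
  runs <- do.call(rbind, rows)
  ## per-cell summary and coexistence flag
  key <- interaction(runs$forcing_period, runs$amplitude, drop = TRUE)
  cells <- do.call(rbind, lapply(split(runs, key), function(d) {
    verdicts <- ifelse(d$locked, paste0(d$p, ":", d$q), "unlocked")
    data.frame(forcing_period = d$forcing_period[1],
               amplitude = d$amplitude[1],
               locked = any(d$locked),
               verdict = paste(sort(unique(verdicts)), collapse = "|"),
               coexistence = length(unique(verdicts)) > 1)
  }))
  cells <- cells[order(cells$amplitude, cells$forcing_period), ]
  rownames(cells) <- NULL
  structure(list(runs = runs, cells = cells, free_period = T0,
                 period_grid = period_grid, amplitude_grid = amplitude_grid,
                 tol_sync = tol_sync),
            class = "entrainment_map")
}

#' Width of a p:q Arnold tongue per amplitude row
#'
#' Counts, for each amplitude, the forcing-period cells whose verdict
#' includes the requested p:q lock.
#'
#' @param map an `entrainment_map`.
#' @param p,q the locking ratio (default 1:1).
#' @return data.frame with `amplitude` and `width` (number of locked cells).
#' @export
tongue_width <- function(map, p = 1, q = 1) {
  lab <- paste0(p, ":", q)
  out <- lapply(split(map$cells, map$cells$amplitude), function(d) {
    data.frame(amplitude = d$amplitude[1],
               width = sum(vapply(strsplit(d$verdict, "|", fixed = TRUE),
                                  function(v) lab %in% v, logical(1))))
  })
  res <- do.call(rbind, out)
  res[order(res$amplitude), ]
}

#' @export
print.entrainment_map <- function(x, ...) {
  cat(sprintf("<entrainment_map> %d periods x %d amplitudes, free period %.2f h\n",
              length(x$period_grid), length(x$amplitude_grid), x$free_period))
  print(x$cells)
  invisible(x)
}

## ---------------------------------------------------------------------------
## Pulse-switch map
## ---------------------------------------------------------------------------

#' Map pulse-induced switching between coexisting attractors
#'
#' Starting on a source limit cycle, applies an instantaneous pulse of each
#' magnitude at each phase of the cycle, lets the system settle, and assigns
#' the destination attractor by nearest fingerprint among the supplied mode
#' set. The zero-magnitude row must map every phase back to the source mode.
#'
#' @param model an `oscillator_model` with coexisting attractors.
#' @param y0_source initial state inside the source basin.
#' @param pulse_var state variable receiving the pulse.
#' @param phase_grid phases (fraction of the source period) in [0, 1).
#' @param magnitude_grid pulse magnitudes (variable units).
#' @param modes list of reference `attractor_fingerprint`s (e.g. census
#'   representatives) defining the destination labels.
#' @param t_settle time to settle onto the source cycle (h).
#' @param t_end integration time after each pulse (h).
#' @param discard post-pulse transient (h).
#' @param threshold assignment threshold on [attractor_distance()].
#' @param cfg an [integrator_config()].
#' @param variable reference variable.
#' @param W waveform grid size.
#' @return a `switch_map`: `cells` data.frame (phase, magnitude, destination
#'   mode id or `"other"`/`"invalid"`), plus the source states per phase.
#' @export
pulse_switch_map <- function(model, y0_source, pulse_var, phase_grid,
                             magnitude_grid, modes,
                             t_settle = 400, t_end = 400, discard = NULL,
                             threshold = 0.05, cfg = integrator_config(),
                             variable = NULL, W = 256) {
  if (!length(modes)) stop("supply at least one reference mode fingerprint")
  free <- integrate_model(model, y0_source, 0, t_settle, cfg)
  v <- variable %||% reference_variable(free)
  fp_src <- fingerprint(free, discard = t_settle * 0.6, variable = v, W = W)
  T0 <- fp_src$period
  src_mode <- nearest_mode(fp_src, modes, threshold)
  ## anchor the phase origin the same way fingerprints do: upward
  ## half-range crossing of the reference variable
  tw <- traj_window(free, from = t_settle - 2 * T0)
  x <- traj_var(tw, v)
  level <- mean(range(x))
  up <- which(x[-length(x)] < level & x[-1] >= level)
  if (!length(up)) stop("no anchor crossing on the source cycle")
  t_anchor <- tw$times[up[1]]
  state_at <- function(phase) {
    tt <- t_anchor + phase * T0
    free$state[which.min(abs(free$times - tt)), ]
  }
  rows <- list()
  src_states <- matrix(NA_real_, length(phase_grid), model$n_vars,
                       dimnames = list(NULL, model$var_labels))
  if (is.null(discard)) discard <- 0.6 * t_end
  for (i in seq_along(phase_grid)) {
    y_ph <- state_at(phase_grid[i])
    src_states[i, ] <- y_ph
    for (m in magnitude_grid) {
      dest <- tryCatch({
        pl <- pulse_spec(pulse_var, m, at = 0)
        tr <- apply_pulse(model, y_ph, pl, t_end, cfg)
        fp <- fingerprint(tr, discard = discard, variable = v, W = W)
        nearest_mode(fp, modes, threshold)
      }, error = function(e) "invalid")
      rows[[length(rows) + 1]] <- data.frame(
        phase = phase_grid[i], magnitude = m, destination = dest)
    }
  }
  cells <- do.call(rbind, rows)
  structure(list(cells = cells, source_mode = src_mode,
                 source_states = src_states, source_period = T0,
                 phase_grid = phase_grid, magnitude_grid = magnitude_grid,
                 threshold = threshold),
            class = "switch_map")
}

nearest_mode <- function(fp, modes, threshold) {
  d <- vapply(modes, function(m) attractor_distance(fp, m), numeric(1))
  i <- which.min(d)
  if (d[i] <= threshold) paste0("M", i) else "other"
}

#' @export
print.switch_map <- function(x, ...) {
  cat(sprintf("<switch_map> source %s (period %.2f h), %d phases x %d magnitudes\n",
              x$source_mode, x$source_period, length(x$phase_grid),
              length(x$magnitude_grid)))
  print(stats::xtabs(~ magnitude + destination, data = x$cells))
  invisible(x)
}
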