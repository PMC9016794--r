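#' Locate local maxima with sub-sample quadratic refinement
#'
#' Strict local maxima of a uniformly sampled signal; each peak time and
#' height is refined by fitting a parabola through the three samples around
#' the maximum. Peaks on the first/last sample are ignored.
#'
#' @param t sample times.
#' @param x signal values.
#' @param min_prominence minimum peak height above the signal minimum, as a
#'   fraction of the signal range (filters numerical ripples).
#' @return data.frame with refined `time` and `height` per peak.
#' @export
find_peaks <- function(t, x, min_prominence = 0.01) {
  n <- length(x)
  if (n < 3) return(data.frame(time = numeric(0), height = numeric(0)))
  i <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
  if (length(i) == 0) return(data.frame(time = numeric(0), height = numeric(0)))
  rng <- range(x)
  keep <- x[i] >= rng[1] + min_prominence * (rng[2] - rng[1])
  i <- i[keep]
  if (length(i) == 0) return(data.frame(time = numeric(0), height = numeric(0)))
  dt <- t[2] - t[1]
  a <- x[i - 1]; b <- x[i]; cc <- x[i + 1]
  denom <- a - 2 * b + cc
  off <- ifelse(abs(denom) > 0, 0.5 * (a - cc) / denom, 0)
  off[abs(off) > 1] <- 0
  data.frame(time = t[i] + off * dt,
             height = b - 0.25 * (a - cc) * off)
}

discard_window <- function(traj, discard) {
  t1 <- traj$times[length(traj$times)]
  if (traj$t0 + discard >= t1 - 2 * traj$dt_out)
    stop("discard window leaves no data")
  traj_window(traj, from = traj$t0 + discard)
}

#' Estimate the oscillation period of one variable
#'
#' Peaks are located on the chosen variable after discarding the transient
#' window, refined to sub-sample precision, and the period is the mean
#' inter-peak interval; its standard deviation over the analysis window is
#' reported alongside. Periods are reported to 0.01 h precision by `print`.
#'
#' @param traj a trajectory.
#' @param variable variable name.
#' @param discard transient window to drop (h, from the trajectory start).
#' @param min_prominence passed to [find_peaks()].
#' @return a `period_estimate` with fields `period` (h), `sd` (h),
#'   `n_cycles`, `variable`.
#' @export
estimate_period <- function(traj, variable, discard = 0,
                            min_prominence = 0.01) {
  tw <- discard_window(traj, discard)
  x <- traj_var(tw, variable)
  if (diff(range(x)) < 1e-7)
    stop("steady state: variable '", variable, "' is flat after the transient")
  pk <- find_peaks(tw$times, x, min_prominence)
  if (nrow(pk) < 3)
    stop("no oscillation: fewer than 3 peaks on '", variable, "'")
  ipi <- diff(pk$time)
  structure(list(period = mean(ipi), sd = stats::sd(ipi),
                 n_cycles = length(ipi), variable = variable),
            class = "period_estimate")
}

#' @export
print.period_estimate <- function(x, ...) {
  cat(sprintf("period %.2f h (sd %.3g h over %d cycles, variable '%s')\n",
              x$period, x$sd, x$n_cycles, x$variable))
  invisible(x)
}

## reference variable of a trajectory: first declared output-port variable
reference_variable <- function(traj) {
  op <- traj$provenance$model$output_ports
  if (length(op)) {
    v <- unlist(op)[1]
    if (v %in% traj$var_labels) return(unname(v))
  }
  traj$var_labels[1]
}

#' Classify the post-transient regime of a trajectory
#'
#' Labels: `steady_state` if the post-transient range of the reference
#' variable is below `tol_flat`; `periodic` if the inter-peak-interval
#' coefficient of variation is below `cv_per` and successive peak heights
#' agree within a relative `tol_amp`; `complex_periodic` if peak intervals
#' and heights repeat with a pattern of 2 to 8 cycles (the pattern length
#' minimizing the mismatch); `aperiodic` otherwise. Aperiodicity is thus
#' diagnosed by elimination, which is sufficient for census purposes.
#'
#' @param traj a trajectory.
#' @param variable variable to classify on (default: reference variable).
#' @param discard transient window (h).
#' @param tol_flat absolute range below which the signal counts as flat.
#' @param cv_per coefficient-of-variation threshold on inter-peak intervals.
#' @param tol_amp relative tolerance on successive peak heights.
#' @param max_pattern longest candidate repeat pattern (cycles).
#' @return one of `"steady_state"`, `"periodic"`, `"complex_periodic"`,
#'   `"aperiodic"`.
#' @export
classify_regime <- function(traj, variable = NULL, discard = 0,
                            tol_flat = 1e-6, cv_per = 1e-3, tol_amp = 1e-2,
                            max_pattern = 8) {
  if (is.null(variable)) variable <- reference_variable(traj)
  tw <- discard_window(traj, discard)
  x <- traj_var(tw, variable)
  if (diff(range(x)) < tol_flat) return("steady_state")
  pk <- find_peaks(tw$times, x)
  if (nrow(pk) < 4) {
    ## a decaying transient tail still counts as settling to steady state;
    ## a clearly oscillatory signal with too few peaks is underdetermined
    if (diff(range(x)) < 100 * tol_flat) return("steady_state")
    stop("insufficient data: fewer than 4 peaks on '", variable,
         "' after the transient")
  }
  ipi <- diff(pk$time)
  h <- pk$height
  amp_scale <- max(abs(h))
  simple <- stats::sd(ipi) / mean(ipi) < cv_per &&
    max(abs(diff(h))) / amp_scale < tol_amp
  if (simple) return("periodic")
  ## look for a repeating pattern of length 2..max_pattern in the joint
  ## (interval, height) sequence
  for (L in 2:max_pattern) {
    if (length(ipi) < 2 * L + 1) break
    d_ipi <- abs(ipi[seq_len(length(ipi) - L)] - ipi[-seq_len(L)])
    d_h <- abs(h[seq_len(length(h) - L)] - h[-seq_len(L)])
    if (max(d_ipi) / mean(ipi) < 10 * cv_per * L &&
        max(d_h) / amp_scale < tol_amp)
      return("complex_periodic")
  }
  "aperiodic"
}

#' Fingerprint the attractor a trajectory has settled onto
#'
#' The unit of attractor identity: period, per-variable amplitude
#' (max - min over the final full cycle) and a normalized one-cycle
#' waveform. The cycle is cut at a defined anchor -- the first upward
#' crossing of the half-range level of the reference variable after the
#' transient -- and resampled to `W` points per variable; each variable's
#' waveform is min-max normalized to [0, 1] (flat variables map to 0.5).
#'
#' @param traj a trajectory with a periodic post-transient regime.
#' @param discard transient window (h).
#' @param variable reference variable (default: first output port).
#' @param W waveform grid size.
#' @param regime optional pre-computed regime label (skips re-classification).
#' @return an `attractor_fingerprint`.
#' @export
fingerprint <- function(traj, discard = 0, variable = NULL, W = 256,
                        regime = NULL) {
  if (is.null(variable)) variable <- reference_variable(traj)
  if (is.null(regime))
    regime <- classify_regime(traj, variable, discard)
  if (regime != "periodic")
    stop("not fingerprintable: regime is '", regime, "'")
  tw <- discard_window(traj, discard)
  pe <- estimate_period(tw, variable, discard = 0)
  x <- traj_var(tw, variable)
  level <- mean(range(x))
  up <- which(x[-length(x)] < level & x[-1] >= level)
  if (length(up) == 0) stop("no anchor crossing found")
  ## last full cycle: anchor at the latest crossing leaving one period
  t_anchor <- tw$times[up] +
    tw$dt_out * (level - x[up]) / (x[up + 1] - x[up])
  t_anchor <- t_anchor[t_anchor + pe$period <=
                         tw$times[length(tw$times)]]
  if (length(t_anchor) == 0) stop("trajectory too short for one full cycle")
  a <- t_anchor[length(t_anchor)]
  grid <- a + pe$period * (0:(W - 1)) / W
  wf <- sapply(seq_along(tw$var_labels), function(j)
    stats::approx(tw$times, tw$state[, j], xout = grid)$y)
  amp <- apply(wf, 2, function(v) diff(range(v)))
  norm <- sapply(seq_len(ncol(wf)), function(j) {
    if (amp[j] < 1e-12) rep(0.5, W)
    else (wf[, j] - min(wf[, j])) / amp[j]
  })
  colnames(norm) <- tw$var_labels
  structure(list(period = pe$period, amplitude = stats::setNames(amp, tw$var_labels),
                 waveform = norm, W = W, regime = "periodic",
                 variable = variable, var_labels = tw$var_labels),
            class = "attractor_fingerprint")
}

#' A degenerate fingerprint for a steady state
#'
#' Used by sweeps when an oscillator loses its rhythm at some step: period
#' NA, zero amplitudes, flat waveform at the resting state.
#'
#' @param state resting state vector (named by variable).
#' @param W waveform grid size.
#' @return an `attractor_fingerprint` with regime `steady_state`.
#' @export
steady_fingerprint <- function(state, W = 256) {
  nv <- length(state)
  labels <- names(state)
  if (is.null(labels)) labels <- paste0("v", seq_len(nv))
  structure(list(period = NA_real_,
                 amplitude = stats::setNames(rep(0, nv), labels),
                 waveform = matrix(0.5, W, nv, dimnames = list(NULL, labels)),
                 W = W, regime = "steady_state", variable = labels[1],
                 var_labels = labels, state = unname(state)),
            class = "attractor_fingerprint")
}

#' @export
print.attractor_fingerprint <- function(x, ...) {
  if (x$regime == "steady_state") {
    cat("<attractor_fingerprint> steady state\n")
  } else {
    cat(sprintf("<attractor_fingerprint> period %.2f h, amplitudes: %s\n",
                x$period,
                paste(sprintf("%s=%.3g", x$var_labels, x$amplitude),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Distance between two attractor fingerprints
#'
#' `d = max(relative period difference, relative amplitude difference,
#' waveform distance)`. The waveform distance is the minimum over cyclic
#' shifts of the RMS difference of the normalized waveforms (averaged over
#' variables); the amplitude term is the largest per-variable relative
#' difference of cycle amplitudes, which separates attractors that share a
#' period and a normalized wave shape but differ in size (concentric cycles
#' of the normal form, for instance). Symmetric, non-negative, zero on
#' identical fingerprints, and invariant to cyclic waveform shifts up to
#' resampling error. Two steady-state fingerprints compare by their resting
#' states; a steady state never matches a periodic fingerprint (distance
#' Inf).
#'
#' @param a,b `attractor_fingerprint`s over the same variable set and `W`.
#' @return non-negative scalar.
#' @export
attractor_distance <- function(a, b) {
  if (!identical(a$var_labels, b$var_labels) || a$W != b$W)
    stop("fingerprints have mismatched variable sets or waveform grids")
  if (a$regime == "steady_state" || b$regime == "steady_state") {
    if (a$regime != b$regime) return(Inf)
    d <- sqrt(mean((a$state - b$state)^2))
    return(d / max(1, sqrt(mean(a$state^2))))
  }
  d_per <- abs(a$period - b$period) / min(a$period, b$period)
  scale <- pmax(a$amplitude, b$amplitude)
  d_amp <- max(ifelse(scale > 0, abs(a$amplitude - b$amplitude) / scale, 0))
  max(d_per, d_amp, waveform_distance(a$waveform, b$waveform))
}

## min over cyclic shifts of the RMS difference between two W x nv waveform
## matrices, via FFT circular cross-correlation:
## rms(s)^2 = (sum A^2 + sum B^2 - 2 sum_j xcorr_j(s)) / (W nv)
waveform_distance <- function(A, B) {
  W <- nrow(A)
  xc <- rowSums(vapply(seq_len(ncol(A)), function(j)
    Re(stats::fft(Conj(stats::fft(B[, j])) * stats::fft(A[, j]),
                  inverse = TRUE)) / W,
    numeric(W)))
  ss <- sum(A^2) + sum(B^2) - 2 * xc
  sqrt(max(0, min(ss)) / (W * ncol(A)))
}

#' Decide whether two variables of one trajectory are p:q locked
#'
#' Periods of both variables are estimated independently after the
#' transient. The pair is locked with ratio p:q (coprime, p, q <= max_ratio)
#' when `|q T_A - p T_B| / (p T_B) < tol_sync` and the peak counts over the
#' window are consistent with p:q. When locked 1:1 the common period is
#' reported as T_A.
#'
#' @param traj a trajectory.
#' @param var_A,var_B variable names (A is the reference oscillator).
#' @param discard transient window (h).
#' @param tol_sync relative tolerance on the period ratio.
#' @param max_ratio largest p or q considered.
#' @return a `sync_result`; if either variable does not oscillate the result
#'   is flagged not-applicable rather than an error (one oscillator may be
#'   suppressed by the coupling).
#' @export
check_sync <- function(traj, var_A, var_B, discard = 0, tol_sync = 1e-2,
                       max_ratio = 4) {
  pe_A <- tryCatch(estimate_period(traj, var_A, discard),
                   error = function(e) NULL)
  pe_B <- tryCatch(estimate_period(traj, var_B, discard),
                   error = function(e) NULL)
  if (is.null(pe_A) || is.null(pe_B)) {
    return(structure(list(locked = FALSE, applicable = FALSE,
                          p = NA_integer_, q = NA_integer_,
                          common_period = NA_real_,
                          period_A = if (is.null(pe_A)) NA_real_ else pe_A$period,
                          period_B = if (is.null(pe_B)) NA_real_ else pe_B$period),
                     class = "sync_result"))
  }
  T_A <- pe_A$period; T_B <- pe_B$period
  best <- NULL
  for (p in 1:max_ratio) for (q in 1:max_ratio) {
    ## frequency ratio f_A : f_B = p : q, i.e. p T_A = q T_B
    if (gcd(p, q) != 1) next
    err <- abs(p * T_A - q * T_B) / (q * T_B)
    ## peak counts over the shared window must be consistent with p:q
    counts_ok <- abs(pe_A$n_cycles * q - pe_B$n_cycles * p) <= max(p, q) + 1
    if (err < tol_sync && counts_ok && (is.null(best) || err < best$err))
      best <- list(p = p, q = q, err = err)
  }
  ## both variables must also be individually rhythmic (not drifting)
  steady <- max(pe_A$sd / T_A, pe_B$sd / T_B) < 10 * tol_sync
  if (!is.null(best) && steady) {
    structure(list(locked = TRUE, applicable = TRUE, p = best$p, q = best$q,
                   common_period = best$p * T_A,
                   period_A = T_A, period_B = T_B),
              class = "sync_result")
  } else {
    structure(list(locked = FALSE, applicable = TRUE,
                   p = NA_integer_, q = NA_integer_,
                   common_period = NA_real_, period_A = T_A, period_B = T_B),
              class = "sync_result")
  }
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

#' @export
print.sync_result <- function(x, ...) {
  if (!x$applicable) {
    cat("<sync_result> not applicable (a variable is non-oscillatory)\n")
  } else if (x$locked) {
    cat(sprintf("<sync_result> locked %d:%d, common period %.2f h (T_A %.2f, T_B %.2f)\n",
                x$p, x$q, x$common_period, x$period_A, x$period_B))
  } else {
    cat(sprintf("<sync_result> not locked (T_A %.2f h, T_B %.2f h)\n",
                x$period_A, x$period_B))
  }
  invisible(x)
}
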