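# ---------------------------------------------------------------------------
# Summary quantities of simulated contractions: action-potential waveform
# features, wavefront speed, refractory interval, and the contracting
# myometrial volume fraction over time.
# ---------------------------------------------------------------------------

# linear interpolation of the time at which v crosses `level`
# direction +1: upward crossing, -1: downward; first crossing after `from`
crossing_time <- function(t, v, level, direction = 1, from = -Inf) {
  dv <- v - level
  if (direction > 0) idx <- which(dv[-1] > 0 & dv[-length(dv)] <= 0)
  else idx <- which(dv[-1] < 0 & dv[-length(dv)] >= 0)
  idx <- idx[t[idx] >= from]
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1]
  f <- dv[i] / (dv[i] - dv[i + 1])
  t[i] + f * (t[i + 1] - t[i])
}

#' Action-potential waveform metrics at a probe
#'
#' Extracts from a transmembrane-potential trace: the peak (most depolarised
#' value), the plateau mean, the duration of the excursion above the resting
#' level before hyperpolarisation, and the resting level used.
#'
#' Definitions: an action potential is detected when the trace exceeds
#' `resting + 0.010` V. The duration is the elapsed time between the upward
#' and the subsequent downward crossing of the resting level (after which
#' the trace undershoots into hyperpolarisation). The plateau level is the
#' median of the post-peak samples above the resting level (so a brief
#' post-upstroke spike does not set it), and the plateau window runs from
#' the first post-peak sample to the downward crossing of a 5 mV band
#' below that level (the onset of rapid repolarisation); the plateau mean
#' averages the samples in that window.
#'
#' @param trace data.frame with columns `t` and `v_m` (or `t` plus one
#'   value column), or a numeric vector with times in `t`
#' @param resting resting potential (V); default the trace's first sample
#' @param t times (s) when `trace` is a bare numeric vector
#' @return a `waveform_metrics` object: list with `ap_detected`, `peak_vm`,
#'   `plateau_mean`, `duration_s`, `resting_vm`, `t_up`, `t_down` (V, s)
#' @export
waveform_metrics <- function(trace, resting = NULL, t = NULL) {
  if (is.data.frame(trace)) {
    tt <- trace$t
    vcol <- setdiff(names(trace), "t")[1]
    v <- trace[[vcol]]
  } else {
    v <- as.numeric(trace)
    tt <- if (is.null(t)) seq_along(v) - 1 else t
  }
  if (is.null(resting)) resting <- v[1]
  out <- list(ap_detected = FALSE, peak_vm = NA_real_,
              plateau_mean = NA_real_, duration_s = NA_real_,
              resting_vm = resting, t_up = NA_real_, t_down = NA_real_)
  class(out) <- "waveform_metrics"
  if (max(v) < resting + 0.010) return(out)  # no AP
  ipk <- which.max(v)
  t_up <- crossing_time(tt, v, resting, +1)
  if (is.na(t_up)) t_up <- tt[1]
  t_down <- crossing_time(tt, v, resting, -1, from = tt[ipk])
  # plateau: post-peak samples up to repolarisation onset. The local plateau
  # level is the median of the post-peak AP body (samples above the resting
  # level); the window ends at the downward crossing of a 5 mV band below
  # that level, so a brief post-upstroke spike does not dominate the mean.
  post <- seq(min(ipk + 1L, length(v)), length(v))
  body_end <- which(v[post] < resting)[1]
  body <- if (is.na(body_end)) post else post[seq_len(max(1L, body_end - 1L))]
  level <- stats::median(v[body])
  stop_i <- which(v[body] < level - 0.005)[1]
  win <- if (is.na(stop_i)) body else body[seq_len(max(1L, stop_i - 1L))]
  out$ap_detected <- TRUE
  out$peak_vm <- v[ipk]
  out$plateau_mean <- mean(v[win])
  out$duration_s <- if (is.na(t_down)) NA_real_ else t_down - t_up
  out$t_up <- t_up; out$t_down <- t_down
  out
}

#' @export
print.waveform_metrics <- function(x, ...) {
  if (!x$ap_detected) {
    cat("waveform_metrics: no action potential detected\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("waveform_metrics: peak %.1f mV, plateau mean %.1f mV, ",
                     "duration %.1f s (resting %.1f mV)\n"),
              1e3 * x$peak_vm, 1e3 * x$plateau_mean, x$duration_s,
              1e3 * x$resting_vm))
  invisible(x)
}

#' Contracting myometrial volume fraction over time
#'
#' Percentage of the myometrial volume whose transmembrane potential is at
#' or above `threshold` (default -40 mV, the excitation threshold `v2`:
#' cells depolarised past it are in the force-generating plateau). Element
#' volumes weight the count; an element counts as contracting when the mean
#' of its vertex values reaches the threshold.
#'
#' @param series [field_series()] of v_m on a myometrial mesh
#' @param mesh optional mesh (default the series' mesh)
#' @param threshold contraction threshold (V)
#' @return data.frame with `t` and `percent` in \[0, 100\]
#' @export
contracting_fraction <- function(series, mesh = NULL, threshold = -0.04) {
  if (is.null(mesh)) mesh <- series$mesh
  onM <- mesh$elem_label == COMPARTMENT_CODES["M"]
  vol <- element_volumes(mesh)[onM]
  el <- mesh$elems[onM, , drop = FALSE]
  if (threshold <= min(series$values[, 1]))
    warning("contracting_fraction: threshold at or below the initial ",
            "(resting) level; the fraction would be 100% at rest")
  tot <- sum(vol)
  pct <- vapply(seq_along(series$times), function(j) {
    v <- series$values[, j]
    ev <- rowMeans(matrix(v[el], nrow = nrow(el)))
    100 * sum(vol[ev >= threshold]) / tot
  }, numeric(1))
  data.frame(t = series$times, percent = pct)
}

#' Minimal stimulus (rheobase-like) duration at fixed amplitude
#'
#' Bisects the duration of a rectangular pulse of amplitude `nu` for the
#' shortest pulse that elicits an action potential from rest.
#'
#' @param params an [ionic_params()]
#' @param nu pulse amplitude (V)
#' @param dt integration step (s)
#' @param range search interval for the duration (s)
#' @return threshold duration (s)
#' @export
excitation_threshold_duration <- function(params, nu = 2, dt = 0.01,
                                          range = c(1e-3, 0.5)) {
  fires <- function(dur) {
    tr <- integrate_space_clamped(params, pulse_drive(params, 1, dur, nu),
                                  t_end = 80, dt = dt)
    max(tr$v_m) > params$v2 + 0.01
  }
  lo <- range[1]; hi <- range[2]
  if (fires(lo)) return(lo)
  if (!fires(hi)) stop("excitation_threshold_duration: amplitude too weak")
  while ((hi - lo) / hi > 0.02) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Refractory interval of the ionic model (0D two-pulse protocol)
#'
#' Applies two identical suprathreshold pulses separated by a variable
#' interval to the space-clamped model and bisects (to `tol`) for the
#' smallest interval at which the second response is a full action
#' potential, defined as peaking within `criterion` of the unconditioned
#' first peak.
#'
#' The default pulse is the pacemaker amplitude (2 V) with duration 1.1
#' times the threshold duration from [excitation_threshold_duration()]:
#' a just-suprathreshold stimulus probes the intrinsic recovery limit of
#' the tissue (stronger stimuli shorten the measured interval by forcing
#' re-excitation of partially recovered membrane).
#'
#' @param params an [ionic_params()]
#' @param nu pulse amplitude (V)
#' @param duration pulse duration (s); default 1.1 x threshold duration
#' @param criterion full-AP criterion on the peak (V); default 5 mV
#' @param tol bisection tolerance on the interval (s)
#' @param t_search upper bound of the search (s)
#' @param dt integration step (s)
#' @return list with `interval` (s; `Inf` with `recovered = FALSE` when no
#'   full second response occurs within `t_search`), `first_peak` (V),
#'   `duration` (pulse length used, s)
#' @export
refractory_period <- function(params, nu = 2, duration = NULL,
                              criterion = 5e-3, tol = 1, t_search = 600,
                              dt = 0.01) {
  if (is.null(duration))
    duration <- 1.1 * excitation_threshold_duration(params, nu, dt)
  p1_trace <- integrate_space_clamped(
    params, pulse_drive(params, 1, duration, nu), t_end = 120, dt = dt)
  first_peak <- max(p1_trace$v_m)
  if (first_peak < params$v2 + 0.01)
    stop("refractory_period: the conditioning pulse does not elicit an AP")
  full_second <- function(gap) {
    dr <- pulse_drive(params, c(1, 1 + gap), duration, nu)
    tr <- integrate_space_clamped(params, dr, t_end = 1 + gap + 90, dt = dt)
    sec <- tr$v_m[tr$t > 1 + gap + duration]
    abs(max(sec) - first_peak) < criterion
  }
  lo <- 2 * duration + tol; hi <- t_search
  if (!full_second(hi))
    return(list(interval = Inf, recovered = FALSE, first_peak = first_peak,
                duration = duration))
  if (full_second(lo))
    return(list(interval = lo, recovered = TRUE, first_peak = first_peak,
                duration = duration))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (full_second(mid)) hi <- mid else lo <- mid
  }
  list(interval = (lo + hi) / 2, recovered = TRUE, first_peak = first_peak,
       duration = duration)
}

#' Recovery time to the resting level after an action potential
#'
#' Time from stimulus onset until the membrane potential, having passed
#' through hyperpolarisation, returns to within `tol` of its equilibrium
#' value. This is the quantity that limits the period of consecutive
#' contractions when re-excitation requires a fully recovered membrane.
#'
#' @param params an [ionic_params()]
#' @param nu,duration stimulus pulse (defaults as in [refractory_period()])
#' @param tol recovery tolerance on v_m (V)
#' @param t_end integration horizon (s)
#' @param dt step (s)
#' @return recovery time (s), or `Inf` if not recovered within `t_end`
#' @export
recovery_time <- function(params, nu = 2, duration = NULL, tol = 5e-4,
                          t_end = 600, dt = 0.01) {
  if (is.null(duration))
    duration <- 1.1 * excitation_threshold_duration(params, nu, dt)
  tr <- integrate_space_clamped(params, pulse_drive(params, 1, duration, nu),
                                t_end = t_end, dt = dt)
  veq <- equilibrium_state(params)$v_m
  imin <- which.min(tr$v_m)  # deepest hyperpolarisation
  after <- seq(imin, nrow(tr))
  hit <- after[abs(tr$v_m[after] - veq) < tol][1]
  if (is.na(hit)) return(Inf)
  tr$t[hit] - 1
}

#' True equilibrium of the space-clamped system
#'
#' Solves \eqn{J_{ion} = 0} on the recovery nullcline, i.e.
#' \eqn{k(v-v_1)(v_2-v)(v-v_3) = (\beta v + \delta)/\gamma}, near the
#' resting potential. (The nominal `v_mr` is the physiological resting
#' value; the model equilibrium lies within a millivolt of it.)
#'
#' @param params an [ionic_params()]
#' @return list with `v_m`, `w` at equilibrium
#' @export
equilibrium_state <- function(params) {
  h <- function(v) params$k * (v - params$v1) * (params$v2 - v) * (v - params$v3) -
    (params$beta * v + params$delta) / params$gamma
  span <- abs(params$v1 - params$v3)
  v <- uniroot(h, c(params$v3 - span, (params$v2 + params$v3) / 2),
               tol = 1e-14)$root
  list(v_m = v, w = (params$beta * v + params$delta) / params$gamma)
}

#' Wavefront speed from probe arrival times
#'
#' Fits arrival time (upstroke crossing of `threshold`) against arc
#' distance along a probe path and reports the slope as the front speed,
#' with the fit's R^2. A warning is raised when R^2 < 0.95 (unreliable
#' fit: front not established across the probes).
#'
#' @param series [field_series()] of v_m
#' @param probe_points n x dim matrix of probe positions ordered along the
#'   propagation path
#' @param threshold upstroke marker (V); default -40 mV
#' @return list with `speed` (m/s), `r_squared`, `arrivals` (data.frame
#'   with arc distance `s` and arrival time `t`)
#' @export
front_speed <- function(series, probe_points, threshold = -0.04) {
  if (is.null(dim(probe_points))) probe_points <- matrix(probe_points, ncol = 1)
  d <- ncol(series$mesh$nodes)
  pp <- probe_points[, seq_len(d), drop = FALSE]
  tr <- probe_trace(series, pp)
  arc <- c(0, cumsum(sqrt(rowSums((pp[-1, , drop = FALSE] -
                                   pp[-nrow(pp), , drop = FALSE])^2))))
  arr <- vapply(seq_len(nrow(pp)), function(i)
    crossing_time(tr$t, tr[[i + 1L]], threshold, +1), numeric(1))
  ok <- !is.na(arr)
  if (sum(ok) < 2) stop("front_speed: front crossed fewer than two probes")
  fit <- lm(arc[ok] ~ arr[ok])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn in summary.lm
  if (is.na(r2) || r2 < 0.95)
    warning("front_speed: low R^2 (", signif(r2, 3), "); fit unreliable")
  list(speed = unname(coef(fit)[2]), r_squared = r2,
       arrivals = data.frame(s = arc, t = arr))
}
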