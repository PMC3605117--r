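#' Ionic model parameters for the myometrial myocyte
#'
#' Container for the constants of the modified FitzHugh-Nagumo ionic model
#' with a plateau-type action potential, together with the membrane constants
#' that couple it to tissue-level propagation. Defaults are the published
#' term-pregnancy parameter set for the human myometrium (resting potential
#' -56 mV, plateau depolarising to about -16 mV).
#'
#' The two membrane current densities of the model are
#' \deqn{J_{ion} = -\frac{1}{\varepsilon_1}\left[k(v_m-v_1)(v_2-v_m)(v_m-v_3) - w\right],}
#' \deqn{\frac{\partial w}{\partial t} = \varepsilon_2(\beta v_m - \gamma w + \delta),}
#' where \eqn{v_m} is the transmembrane potential (V) and \eqn{w} a recovery
#' variable (V). \eqn{\varepsilon_1} (Ohm m^2) sets the sharpness of the
#' action-potential edges, \eqn{\varepsilon_2} (1/s) the duration,
#' \eqn{v_1 > v_2 > v_3} (V) and \eqn{k} (1/V^2) the voltage range, and the
#' ratios \eqn{\beta/\gamma}, \eqn{\delta/\gamma} the excitation threshold.
#'
#' Unit convention: \code{ionic_current()} and \code{stimulus_current()}
#' return membrane current per unit membrane area (A/m^2). The corresponding
#' volume current density (A/m^3) used in the tissue equations is obtained by
#' multiplying by the surface-to-volume ratio \code{a_m}; all integrators in
#' this package apply that factor internally, so the 0D balance reads
#' \eqn{c_m\,dv_m/dt = -J_{ion} + J_{stim}}.
#'
#' @param eps1 edge-sharpness resistivity constant (Ohm m^2)
#' @param eps2 recovery rate constant (1/s)
#' @param k cubic coefficient (1/V^2)
#' @param v1,v2,v3 cubic root potentials (V), must satisfy `v3 < v2 < v1`
#' @param delta recovery offset (V)
#' @param gamma recovery self-coupling (dimensionless)
#' @param beta recovery voltage coupling (dimensionless)
#' @param c_m membrane capacitance per unit area (F/m^2)
#' @param a_m membrane surface-to-volume ratio (1/m); the default is the
#'   closed-cylinder value for a 7 um x 450 um myocyte, see
#'   [surface_to_volume()]
#' @param v_mr resting transmembrane potential (V)
#' @return an object of class `ionic_params` (a validated named list)
#' @seealso [ionic_current()], [recovery_rate()], [resting_state()],
#'   [nullcline_fixed_points()], [integrate_space_clamped()]
#' @export
#' @examples
#' p <- ionic_params()
#' resting_state(p)
ionic_params <- function(eps1 = 200, eps2 = 0.09, k = 1e4,
                         v1 = -0.02, v2 = -0.04, v3 = -0.065,
                         delta = 0.052, gamma = 0.1, beta = 1,
                         c_m = 0.01, a_m = surface_to_volume(7e-6, 450e-6),
                         v_mr = -0.056) {
  p <- list(eps1 = eps1, eps2 = eps2, k = k, v1 = v1, v2 = v2, v3 = v3,
            delta = delta, gamma = gamma, beta = beta,
            c_m = c_m, a_m = a_m, v_mr = v_mr)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("ionic_params: '", nm, "' must be a finite numeric scalar")
  }
  if (eps1 <= 0) stop("ionic_params: eps1 must be > 0")
  if (eps2 <= 0) stop("ionic_params: eps2 must be > 0")
  if (k <= 0) stop("ionic_params: k must be > 0")
  if (c_m <= 0) stop("ionic_params: c_m must be > 0")
  if (a_m <= 0) stop("ionic_params: a_m must be > 0")
  if (!(v3 < v2 && v2 < v1))
    stop("ionic_params: root ordering v3 < v2 < v1 violated (",
         v3, ", ", v2, ", ", v1, ")")
  structure(p, class = "ionic_params")
}

#' @export
print.ionic_params <- function(x, ...) {
  cat("Modified FitzHugh-Nagumo ionic parameters\n")
  cat(sprintf("  eps1 = %g Ohm m^2, eps2 = %g 1/s, k = %g 1/V^2\n",
              x$eps1, x$eps2, x$k))
  cat(sprintf("  cubic roots (v1, v2, v3) = (%g, %g, %g) V\n", x$v1, x$v2, x$v3))
  cat(sprintf("  recovery: beta = %g, gamma = %g, delta = %g V\n",
              x$beta, x$gamma, x$delta))
  cat(sprintf("  membrane: c_m = %g F/m^2, a_m = %g 1/m, v_mr = %g V\n",
              x$c_m, x$a_m, x$v_mr))
  invisible(x)
}

#' Surface-to-volume ratio of a closed cylindrical myocyte
#'
#' For a closed cylinder of diameter `d_cell` and length `l_cell`,
#' area/volume = 4/d + 2/l.
#'
#' @param d_cell cell diameter (m)
#' @param l_cell cell length (m)
#' @return surface-to-volume ratio (1/m)
#' @export
#' @examples
#' surface_to_volume(7e-6, 450e-6)  # ~5.7587e5 1/m
surface_to_volume <- function(d_cell, l_cell) {
  if (any(d_cell <= 0) || any(l_cell <= 0))
    stop("surface_to_volume: d_cell and l_cell must be > 0")
  4 / d_cell + 2 / l_cell
}

#' Ionic membrane current density
#'
#' Evaluates the cubic ionic current of the modified FitzHugh-Nagumo model,
#' \eqn{J_{ion} = -(1/\varepsilon_1)[k(v_m-v_1)(v_2-v_m)(v_m-v_3) - w]},
#' in A/m^2 (per unit membrane area; multiply by `a_m` for A/m^3).
#' Vectorised over the state.
#'
#' @param state list (or `ionic_state`) with numeric `v_m` and `w` (V)
#' @param params an [ionic_params()] object
#' @return ionic current density, same length as `state$v_m`
#' @export
ionic_current <- function(state, params) {
  v <- state$v_m; w <- state$w
  cubic <- params$k * (v - params$v1) * (params$v2 - v) * (v - params$v3)
  -(cubic - w) / params$eps1
}

#' Recovery-variable rate
#'
#' \eqn{dw/dt = \varepsilon_2(\beta v_m - \gamma w + \delta)}; the recovery
#' variable controls the action-potential duration and the post-repolarisation
#' hyperpolarisation. Vectorised.
#'
#' @inheritParams ionic_current
#' @return dw/dt (V/s)
#' @export
recovery_rate <- function(state, params) {
  params$eps2 * (params$beta * state$v_m - params$gamma * state$w + params$delta)
}

#' Pacemaker stimulus specification
#'
#' A pacemaker is an amplitude `nu` (V) together with a spatio-temporal
#' indicator-type support `h(r, t)` with values in \[0, 1\]. The stimulus
#' current contributed by a set of pacemakers is
#' \eqn{J_{stim}(r,t) = (1/\varepsilon_1)\sum_i \nu_i h_i(r,t)} (A/m^2).
#'
#' @param nu stimulus amplitude (V)
#' @param support function of `(r, t)` where `r` is an n x 3 matrix of
#'   positions (m) and `t` a scalar time (s); must return values in \[0, 1\]
#'   of length `nrow(r)`
#' @return a `pacemaker_spec` object
#' @seealso [fundus_pacemaker()] for the spherical-fundus example
#' @export
pacemaker_spec <- function(nu, support) {
  if (!is.function(support)) stop("pacemaker_spec: support must be a function(r, t)")
  if (!is.numeric(nu) || length(nu) != 1L) stop("pacemaker_spec: nu must be scalar")
  structure(list(nu = nu, support = support), class = "pacemaker_spec")
}

#' Fundus pacemaker of the spherical myometrium example
#'
#' Indicator support active for `t_on <= t <= t_off` on the spherical-cap
#' band `r_min <= ||r|| <= r_max`, `z >= z_min` (the uterine fundus of the
#' 16 cm spherical myometrium), with amplitude `nu`.
#'
#' @param nu amplitude (V)
#' @param t_on,t_off stimulus window (s)
#' @param r_min,r_max radial band (m)
#' @param z_min cap height (m)
#' @return a [pacemaker_spec()] object
#' @export
fundus_pacemaker <- function(nu = 2, t_on = 0, t_off = 0.1,
                             r_min = 0.15, r_max = 0.16, z_min = 0.15) {
  pacemaker_spec(nu, function(r, t) {
    r <- as_points3(r)
    if (t < t_on || t > t_off) return(numeric(nrow(r)))
    rad <- sqrt(rowSums(r^2))
    as.numeric(rad >= r_min & rad <= r_max & r[, 3] >= z_min)
  })
}

# coerce a vector or matrix to an n x 3 coordinate matrix
as_points3 <- function(r) {
  if (is.null(dim(r))) r <- matrix(r, nrow = 1L)
  if (ncol(r) < 3L) r <- cbind(r, matrix(0, nrow(r), 3L - ncol(r)))
  r
}

#' Stimulus current density from pacemaker areas
#'
#' \eqn{J_{stim}(r,t) = (1/\varepsilon_1)\sum_i \nu_i h_i(r,t)} in A/m^2;
#' additive over pacemakers.
#'
#' @param position n x 3 matrix (or length-3 vector) of positions (m)
#' @param time scalar time (s)
#' @param pacemakers list of [pacemaker_spec()] objects (a single spec is
#'   accepted)
#' @param params an [ionic_params()] object (supplies `eps1`)
#' @return stimulus current density, length `nrow(position)`
#' @export
stimulus_current <- function(position, time, pacemakers, params) {
  position <- as_points3(position)
  if (inherits(pacemakers, "pacemaker_spec")) pacemakers <- list(pacemakers)
  out <- numeric(nrow(position))
  for (pm in pacemakers) {
    h <- pm$support(position, time)
    if (any(h < -1e-12 | h > 1 + 1e-12))
      stop("stimulus_current: pacemaker support outside [0, 1]")
    out <- out + pm$nu * h
  }
  out / params$eps1
}

#' Resting state of the ionic model
#'
#' The initial condition of the tissue simulations: `v_m = v_mr` and the
#' recovery variable on its nullcline at rest,
#' `w = (beta * v_mr + delta) / gamma`.
#'
#' @inheritParams ionic_current
#' @return list with `v_m` and `w` (class `ionic_state`)
#' @export
resting_state <- function(params) {
  if (params$gamma == 0) stop("resting_state: gamma must be nonzero")
  structure(list(v_m = params$v_mr,
                 w = (params$beta * params$v_mr + params$delta) / params$gamma),
            class = "ionic_state")
}

#' Roots of the frozen-recovery cubic
#'
#' The traveling-front analysis of the monodomain equation freezes the
#' recovery variable at its resting value, leaving the cubic
#' \deqn{f(v) = (v-v_1)(v_2-v)(v-v_3) - \frac{\beta v_{mr}+\delta}{k\gamma},}
#' whose three real roots \eqn{v_1^* < v_2^* < v_3^*} are the effective
#' resting, threshold and excited potentials that enter the front-speed
#' formula and the anisotropy-ratio calibration. Roots are found with the
#' companion-matrix method (`polyroot`) and polished by Newton iteration.
#'
#' @inheritParams ionic_current
#' @return numeric vector of the three roots in ascending order (V)
#' @export
#' @examples
#' nullcline_fixed_points(ionic_params())  # approx (-0.0600, -0.0485, -0.0165)
nullcline_fixed_points <- function(params) {
  # f(v) = -(v^3 + c2 v^2 + c1 v + c0') with the frozen-w constant folded in
  v1 <- params$v1; v2 <- params$v2; v3 <- params$v3
  const <- (params$beta * params$v_mr + params$delta) / (params$k * params$gamma)
  # (v-v1)(v2-v)(v-v3) = -(v^3 - (v1+v2+v3) v^2 + (v1 v2 + v1 v3 + v2 v3) v - v1 v2 v3)
  a2 <- -(v1 + v2 + v3)
  a1 <- v1 * v2 + v1 * v3 + v2 * v3
  a0 <- -(v1 * v2 * v3) + const   # roots of v^3 + a2 v^2 + a1 v + a0 = 0
  disc <- 18 * a2 * a1 * a0 - 4 * a2^3 * a0 + a2^2 * a1^2 - 4 * a1^3 - 27 * a0^2
  if (disc < 0)
    stop("nullcline_fixed_points: cubic has complex roots (discriminant = ",
         signif(disc, 6), "); parameterisation is not excitable")
  z <- polyroot(c(a0, a1, a2, 1))
  r <- sort(Re(z))
  # Newton polish
  f <- function(v) v^3 + a2 * v^2 + a1 * v + a0
  fp <- function(v) 3 * v^2 + 2 * a2 * v + a1
  for (i in 1:3) {
    for (it in 1:8) {
      step <- f(r[i]) / fp(r[i])
      if (!is.finite(step)) break
      r[i] <- r[i] - step
      if (abs(step) < 1e-16) break
    }
  }
  scale <- max(abs(c(a0, a1, a2, 1)))
  if (any(abs(f(r)) > 1e-12 * scale))
    stop("nullcline_fixed_points: root polish failed")
  r
}

#' Space-clamped (0D) integration of the ionic model
#'
#' Integrates the membrane balance
#' \eqn{c_m\, dv_m/dt = -J_{ion} + J_{drive}(t)}, \eqn{dw/dt} per
#' [recovery_rate()], from the resting state, with a fixed-step implicit
#' BDF2 scheme (BDF1 startup, damped Newton) suited to the model's stiff
#' upstroke, or optionally classical RK4.
#'
#' @param params an [ionic_params()] object
#' @param drive function of time returning the stimulus current density
#'   \eqn{J_{stim}(t)} in A/m^2 (e.g. [pulse_drive()]), or `NULL` for none
#' @param t_end end time (s)
#' @param dt fixed step (s); default 1 ms
#' @param method `"bdf2"` (default) or `"rk4"`
#' @param state0 optional initial `list(v_m, w)`; default [resting_state()]
#' @param output_stride keep every `output_stride`-th step in the returned
#'   trajectory (the integration itself always uses `dt`)
#' @return data.frame with columns `t`, `v_m`, `w`
#' @export
#' @examples
#' p <- ionic_params()
#' tr <- integrate_space_clamped(p, pulse_drive(p, t_on = 1, duration = 0.02),
#'                               t_end = 60, dt = 0.01)
#' max(tr$v_m)  # plateau peak near -0.017 V
integrate_space_clamped <- function(params, drive = NULL, t_end, dt = 1e-3,
                                    method = c("bdf2", "rk4"),
                                    state0 = NULL, output_stride = 1L) {
  method <- match.arg(method)
  if (!is.finite(t_end) || t_end <= 0) stop("integrate_space_clamped: t_end must be finite and > 0")
  if (dt <= 0) stop("integrate_space_clamped: dt must be > 0")
  if (is.null(drive)) drive <- function(t) 0
  s0 <- if (is.null(state0)) resting_state(params) else state0
  n <- ceiling(t_end / dt)
  keep <- seq(0L, n, by = as.integer(output_stride))
  tt <- numeric(length(keep)); vv <- numeric(length(keep)); ww <- numeric(length(keep))
  v <- s0$v_m; w <- s0$w
  tt[1] <- 0; vv[1] <- v; ww[1] <- w
  ik <- 2L
  e1 <- params$eps1; e2 <- params$eps2; k <- params$k
  p1 <- params$v1; p2 <- params$v2; p3 <- params$v3
  be <- params$beta; ga <- params$gamma; de <- params$delta; cm <- params$c_m
  fv <- function(v, w, J) ((k * (v - p1) * (p2 - v) * (v - p3) - w) / e1 + J) / cm
  fw <- function(v, w) e2 * (be * v - ga * w + de)
  # analytic Jacobian entries for Newton
  dfv_dv <- function(v) (k * (-3 * v^2 + 2 * (p1 + p2 + p3) * v -
                               (p1 * p2 + p1 * p3 + p2 * p3)) / e1) / cm
  dfv_dw <- -1 / (e1 * cm)
  dfw_dv <- e2 * be
  dfw_dw <- -e2 * ga
  vm1 <- v; wm1 <- w  # previous step (for BDF2)
  for (i in seq_len(n)) {
    t1 <- i * dt
    if (method == "rk4") {
      t0 <- t1 - dt
      J1 <- drive(t0); J2 <- drive(t0 + dt / 2); J4 <- drive(t1)
      k1v <- fv(v, w, J1);                         k1w <- fw(v, w)
      k2v <- fv(v + dt / 2 * k1v, w + dt / 2 * k1w, J2); k2w <- fw(v + dt / 2 * k1v, w + dt / 2 * k1w)
      k3v <- fv(v + dt / 2 * k2v, w + dt / 2 * k2w, J2); k3w <- fw(v + dt / 2 * k2v, w + dt / 2 * k2w)
      k4v <- fv(v + dt * k3v, w + dt * k3w, J4);   k4w <- fw(v + dt * k3v, w + dt * k3w)
      vn <- v + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
      wn <- w + dt / 6 * (k1w + 2 * k2w + 2 * k3w + k4w)
    } else {
      # BDF1 for the first step, BDF2 afterwards:
      #   BDF2: y_n - 4/3 y_{n-1} + 1/3 y_{n-2} = (2/3) dt f(y_n)
      J <- drive(t1)
      if (i == 1L) { av <- v; aw <- w; cdt <- dt }
      else { av <- (4 * v - vm1) / 3; aw <- (4 * w - wm1) / 3; cdt <- 2 * dt / 3 }
      vn <- v; wn <- w
      for (it in 1:30) {
        Rv <- vn - av - cdt * fv(vn, wn, J)
        Rw <- wn - aw - cdt * fw(vn, wn)
        a11 <- 1 - cdt * dfv_dv(vn); a12 <- -cdt * dfv_dw
        a21 <- -cdt * dfw_dv;        a22 <- 1 - cdt * dfw_dw
        det <- a11 * a22 - a12 * a21
        dv <- (Rv * a22 - a12 * Rw) / det
        dw <- (a11 * Rw - Rv * a21) / det
        vn <- vn - dv; wn <- wn - dw
        if (abs(dv) < 1e-13 && abs(dw) < 1e-13) break
      }
    }
    if (!is.finite(vn) || abs(vn) > 1)
      stop("integrate_space_clamped: instability at t = ", t1,
           " (|v_m| > 1 V); reduce dt")
    vm1 <- v; wm1 <- w; v <- vn; w <- wn
    if (ik <= length(keep) && i == keep[ik]) {
      tt[ik] <- t1; vv[ik] <- v; ww[ik] <- w; ik <- ik + 1L
    }
  }
  data.frame(t = tt, v_m = vv, w = ww)
}

#' Rectangular stimulus drive for 0D integration
#'
#' Returns \eqn{J_{stim}(t) = (\nu/\varepsilon_1)} for
#' `t_on <= t < t_on + duration` (summed over possibly several onsets),
#' matching the pacemaker stimulus model evaluated inside its support.
#'
#' @param params an [ionic_params()] object
#' @param t_on onset time(s) (s); may be a vector for repeated pulses
#' @param duration pulse duration (s)
#' @param nu amplitude (V)
#' @return function of time suitable for [integrate_space_clamped()]
#' @export
pulse_drive <- function(params, t_on, duration, nu = 2) {
  force(t_on); force(duration); force(nu)
  e1 <- params$eps1
  function(t) sum((nu / e1) * (t >= t_on & t < t_on + duration))
}

#' Convergence check utility for the 0D integrator
#'
#' Integrates at `dt` and `dt/2` and reports the maximum absolute
#' difference in `v_m` at the coarse time points; useful to verify first-order
#' (or better) convergence of the fixed-step schemes.
#'
#' @inheritParams integrate_space_clamped
#' @return list with `dt`, `max_diff_v` (V)
#' @export
integration_convergence <- function(params, drive, t_end, dt = 1e-2,
                                    method = "bdf2") {
  a <- integrate_space_clamped(params, drive, t_end, dt, method)
  b <- integrate_space_clamped(params, drive, t_end, dt / 2, method,
                               output_stride = 2L)
  m <- min(nrow(a), nrow(b))
  list(dt = dt, max_diff_v = max(abs(a$v_m[1:m] - b$v_m[1:m])))
}
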