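#' Time-stepping controls for the monodomain solver
#'
#' @param dt time step (s); default 10 ms
#' @param t_end end time (s)
#' @param tolerance linear-solver tolerance; the solver uses a sparse
#'   Cholesky factorisation (direct), so this only guards the residual check
#' @param output_stride keep every k-th step in the output series
#' @param mass_lumping use a lumped mass matrix (default) or consistent mass
#' @param seed recorded for provenance (the scheme is deterministic)
#' @param max_dt_halvings automatic step halvings on detected instability
#' @return a `solver_config` object
#' @export
solver_config <- function(dt = 0.01, t_end, tolerance = 1e-8,
                          output_stride = 10L, mass_lumping = TRUE,
                          seed = NULL, max_dt_halvings = 3L) {
  if (dt <= 0) stop("solver_config: dt must be > 0")
  if (t_end <= dt) stop("solver_config: t_end must exceed dt")
  if (tolerance <= 0) stop("solver_config: tolerance must be > 0")
  structure(list(dt = dt, t_end = t_end, tolerance = tolerance,
                 output_stride = as.integer(output_stride),
                 mass_lumping = isTRUE(mass_lumping), seed = seed,
                 max_dt_halvings = as.integer(max_dt_halvings)),
            class = "solver_config")
}

#' Assemble monodomain mass and stiffness operators
#'
#' Discretises \eqn{\nabla\cdot(\frac{\varsigma}{\varsigma+1} G_e' \nabla\,\cdot)}
#' with P1 elements on a myometrial mesh. The stiffness matrix is symmetric
#' with the constants as its null space (natural no-flux boundary
#' conditions); the mass operator is positive definite.
#'
#' @param mesh a `uw_mesh` whose elements are all myometrium
#' @param tensor_field extracellular conductivity: a `tensor_field` from
#'   [assemble_tensor_field()], a scalar (1D cable: sigma_el along the
#'   fiber), or a per-element array
#' @param varsigma equal-anisotropy ratio
#' @param params an [ionic_params()] (supplies `a_m`, `c_m`)
#' @param mass_lumping lumped (vector) or consistent (sparse) mass
#' @return list with `K` (stiffness), `M` (lumped mass vector or sparse
#'   matrix), `mesh`, `params`, `varsigma`, `grads`
#' @export
assemble_operators <- function(mesh, tensor_field, varsigma, params,
                               mass_lumping = TRUE) {
  if (!all(mesh$elem_label == COMPARTMENT_CODES["M"]))
    stop("assemble_operators: all elements must be labelled M (myometrium)")
  grads <- p1_gradients(mesh)
  G <- element_tensors(mesh, tensor_field)
  # SPD check at each element
  for (k in seq_len(dim(G)[3])) {
    ev <- eigen(G[, , k], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("assemble_operators: conductivity tensor not positive definite ",
           "at element ", k, " (min eigenvalue ", signif(min(ev), 4), ")")
  }
  fac <- varsigma / (varsigma + 1)
  K <- assemble_stiffness(mesh, G * fac, grads = grads)
  M <- if (mass_lumping) lumped_mass(mesh) else consistent_mass(mesh)
  list(K = K, M = M, mesh = mesh, params = params, varsigma = varsigma,
       grads = grads, mass_lumping = mass_lumping)
}

#' Run the monodomain reaction-diffusion simulation
#'
#' Solves \eqn{a_m c_m \partial_t v_m = \nabla\cdot(\frac{\varsigma}{\varsigma+1}
#' G_e'\nabla v_m) + a_m(-J_{ion} + J_{stim})} with no-flux boundaries from
#' the resting initial state, using an IMEX scheme: implicit (backward-Euler)
#' diffusion, explicit reaction. The recovery variable advances explicitly.
#' On detected instability (|v_m| > 1 V) the step is halved automatically,
#' up to `max_dt_halvings` times.
#'
#' @param mesh myometrial mesh (used for stimulus evaluation; must match the
#'   operators)
#' @param operators output of [assemble_operators()]
#' @param params an [ionic_params()]
#' @param pacemakers list of [pacemaker_spec()] (possibly empty)
#' @param config a [solver_config()]
#' @param store_w also return the recovery-variable series
#' @param progress optional function(step, time, vrange) for logging
#' @return list with `v_m` (a [field_series()]), `w` (if requested), and the
#'   `dt` actually used
#' @export
run_monodomain <- function(mesh, operators, params, pacemakers = list(),
                           config, store_w = FALSE, progress = NULL) {
  dt <- config$dt
  for (attempt in 0:config$max_dt_halvings) {
    out <- tryCatch(
      run_monodomain_fixed(mesh, operators, params, pacemakers, config, dt,
                           store_w, progress),
      uw_instability = function(e) NULL)
    if (!is.null(out)) return(out)
    dt <- dt / 2
  }
  stop("run_monodomain: unstable even after ", config$max_dt_halvings,
       " step halvings; refine the mesh or reduce dt")
}

run_monodomain_fixed <- function(mesh, operators, params, pacemakers, config,
                                 dt, store_w, progress) {
  n <- nrow(mesh$nodes)
  amcm <- params$a_m * params$c_m
  K <- operators$K
  lumped <- operators$mass_lumping
  if (lumped) {
    Mv <- operators$M
    A <- Matrix::Diagonal(x = amcm * Mv) + dt * K
  } else {
    Mm <- operators$M
    A <- amcm * Mm + dt * K
  }
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  rest <- resting_state(params)
  v <- rep(rest$v_m, n); w <- rep(rest$w, n)
  nt <- ceiling(config$t_end / dt)
  keep <- unique(c(seq(0L, nt, by = config$output_stride), nt))
  times <- keep * dt
  V <- matrix(0, n, length(keep)); V[, 1] <- v
  W <- if (store_w) matrix(0, n, length(keep)) else NULL
  if (store_w) W[, 1] <- w
  ik <- 2L
  nodes3 <- as_points3(mesh$nodes)
  e1 <- params$eps1; k_ <- params$k
  p1 <- params$v1; p2 <- params$v2; p3 <- params$v3
  has_stim <- length(pacemakers) > 0L
  for (it in seq_len(nt)) {
    t0 <- (it - 1L) * dt
    cub <- k_ * (v - p1) * (p2 - v) * (v - p3)
    react <- (cub - w) / e1
    if (has_stim) react <- react + stimulus_current(nodes3, t0, pacemakers, params)
    react <- params$a_m * react
    if (lumped) {
      rhs <- amcm * Mv * v + dt * (Mv * react)
    } else {
      rhs <- amcm * (Mm %*% v) + dt * (Mm %*% react)
    }
    v <- as.numeric(Matrix::solve(ch, rhs))
    w <- w + dt * params$eps2 * (params$beta * v - params$gamma * w + params$delta)
    if (!all(is.finite(v)) || max(abs(v)) > 1) {
      cond <- structure(class = c("uw_instability", "error", "condition"),
                        list(message = paste0("instability at t = ", it * dt),
                             call = NULL))
      stop(cond)
    }
    if (!is.null(progress) && it %% 500L == 0L)
      progress(it, it * dt, range(v))
    if (ik <= length(keep) && it == keep[ik]) {
      V[, ik] <- v
      if (store_w) W[, ik] <- w
      ik <- ik + 1L
    }
  }
  out <- list(v_m = field_series(times, V, mesh, "v_m", "V"), dt = dt)
  if (store_w) out$w <- field_series(times, W, mesh, "w", "V")
  out
}

#' One-dimensional monodomain cable simulation
#'
#' Convenience wrapper: builds a uniform cable, applies a rectangular
#' end stimulus (the 1D analogue of a fundus pacemaker), runs the monodomain
#' scheme and measures the front speed from upstroke arrival times
#' (crossings of the `v2` excitation threshold) at probes spanning the
#' central half of the cable.
#'
#' @param params an [ionic_params()]
#' @param sigma_el longitudinal extracellular conductivity (S/m)
#' @param varsigma equal-anisotropy ratio
#' @param length cable length (m)
#' @param resolution element size (m)
#' @param dt time step (s)
#' @param t_end end time (s); if `NULL`, chosen from the closed-form speed
#'   estimate so the front can cross the cable (capped at `t_max`)
#' @param t_max cap for the automatic end time (s)
#' @param stim_width stimulated region at the x = 0 end (m)
#' @param stim_nu,stim_duration stimulus amplitude (V) and duration (s)
#' @param probe_x optional probe position for a returned trace (m)
#' @param output_stride output thinning for the stored series
#' @return list with `speed` (m/s), `r_squared`, `arrivals` (data.frame),
#'   `trace` (data.frame t, v_m at `probe_x`), `series`, `mesh`, `dt`
#' @export
simulate_cable <- function(params, sigma_el, varsigma, length = 0.2,
                           resolution = 1e-3, dt = 0.01, t_end = NULL,
                           t_max = 400, stim_width = 0.01, stim_nu = 2,
                           stim_duration = 0.1, probe_x = length / 2,
                           output_stride = 10L) {
  mesh <- mesh_cable(length, resolution)
  ops <- assemble_operators(mesh, sigma_el, varsigma, params)
  if (is.null(t_end)) {
    c_est <- front_speed_closed_form(varsigma, params, sigma_el)
    t_end <- min(t_max, 1.6 * (0.8 * length) / max(c_est, 1e-6) + 30)
  }
  pm <- pacemaker_spec(stim_nu, function(r, t) {
    if (t < 0 || t > stim_duration) return(numeric(nrow(r)))
    as.numeric(r[, 1] <= stim_width)
  })
  cfg <- solver_config(dt = dt, t_end = t_end, output_stride = output_stride)
  sol <- run_monodomain(mesh, ops, params, list(pm), cfg)
  ser <- sol$v_m
  probes <- seq(0.25 * length, 0.75 * length, by = 0.01)
  x <- mesh$nodes[, 1]
  pids <- vapply(probes, function(s) which.min(abs(x - s)), 1L)
  thr <- params$v2
  arr <- rep(NA_real_, length(pids))
  for (i in seq_along(pids)) {
    tv <- ser$values[pids[i], ]
    ix <- which(tv[-1] >= thr & tv[-length(tv)] < thr)[1]
    if (!is.na(ix)) {
      t0 <- ser$times[ix]; t1 <- ser$times[ix + 1]
      f <- (thr - tv[ix]) / (tv[ix + 1] - tv[ix])
      arr[i] <- t0 + f * (t1 - t0)
    }
  }
  ok <- !is.na(arr)
  if (sum(ok) >= 3) {
    fit <- lm(probes[ok] ~ arr[ok])
    speed <- unname(coef(fit)[2])
    r2 <- suppressWarnings(summary(fit)$r.squared)
  } else {
    # front did not reach enough probes: report covered distance over time
    reached <- ser$values[, ncol(ser$values)] >= thr
    speed <- (max(c(0, x[reached])) - stim_width) / t_end
    r2 <- NA_real_
  }
  trace <- probe_trace(ser, matrix(probe_x, 1, 1))
  names(trace)[2] <- "v_m"
  list(speed = speed, r_squared = r2,
       arrivals = data.frame(x = probes, t = arr),
       trace = trace, series = ser, mesh = mesh, dt = sol$dt)
}
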