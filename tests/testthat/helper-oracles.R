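# Analytic oracles and shared (lazily built) simulation fixtures.

# published term-pregnancy parameter set (the package defaults restate it;
# spelled out here so the tests do not depend on the defaults)
table_params <- function(...) {
  base <- list(eps1 = 200, eps2 = 0.09, k = 1e4,
               v1 = -0.02, v2 = -0.04, v3 = -0.065,
               delta = 0.052, gamma = 0.1, beta = 1,
               c_m = 0.01, a_m = surface_to_volume(7e-6, 450e-6),
               v_mr = -0.056)
  do.call(ionic_params, utils::modifyList(base, list(...)))
}

# --- analytic oracles ------------------------------------------------------

# surface potential of a current dipole at b on the +z axis inside an
# insulated homogeneous sphere (radius R, conductivity sigma); moment has a
# radial (z) component pr and a tangential (x) component pt. Legendre series
# with Condon-Shortley P_n^1; the n = 1 term reproduces the closed-form
# centre-dipole potential, which anchors the sign conventions.
oracle_dipole_sphere_surface <- function(R, sigma, b, pr, pt, theta, phi0,
                                         nmax = 80) {
  ct <- cos(theta)
  P <- numeric(nmax + 1); P[1] <- 1; P[2] <- ct
  P1 <- numeric(nmax + 1); P1[1] <- 0; P1[2] <- -sqrt(max(0, 1 - ct^2))
  for (n in 2:nmax) {
    P[n + 1] <- ((2 * n - 1) * ct * P[n] - (n - 1) * P[n - 1]) / n
    P1[n + 1] <- ((2 * n - 1) * ct * P1[n] - n * P1[n - 1]) / (n - 1)
  }
  s <- 0
  for (n in 1:nmax) {
    coef <- (2 * n + 1) / n * (b^(n - 1) / R^(n + 1))
    s <- s + coef * (n * pr * P[n + 1] - pt * P1[n + 1] * cos(phi0))
  }
  s / (4 * pi * sigma)
}

# magnetic field outside a spherically symmetric conductor from a current
# dipole q at r0 (closed form for the sphere model)
oracle_sarvas <- function(q, r0, r) {
  a_v <- r - r0; a <- sqrt(sum(a_v^2)); rn <- sqrt(sum(r^2))
  F <- a * (rn * a + rn^2 - sum(r0 * r))
  gF <- (a^2 / rn + sum(a_v * r) / a + 2 * a + 2 * rn) * r -
    (a + 2 * rn + sum(a_v * r) / a) * r0
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  1e-7 * (F * qxr0 - sum(qxr0 * r) * gF) / F^2
}

# reference 0D integration via deSolve (adaptive lsoda), independent of the
# package's fixed-step schemes
oracle_integrate_0d <- function(params, drive, t_end, times = NULL) {
  skip_if_not_installed("deSolve")
  if (is.null(times)) times <- seq(0, t_end, by = 0.05)
  rhs <- function(t, y, parms) {
    v <- y[1]; w <- y[2]
    cub <- params$k * (v - params$v1) * (params$v2 - v) * (v - params$v3)
    dv <- ((cub - w) / params$eps1 + drive(t)) / params$c_m
    dw <- params$eps2 * (params$beta * v - params$gamma * w + params$delta)
    list(c(dv, dw))
  }
  r0 <- resting_state(params)
  out <- deSolve::lsoda(c(v = r0$v_m, w = r0$w), times, rhs, NULL,
                        rtol = 1e-9, atol = 1e-12)
  data.frame(t = out[, 1], v_m = out[, 2], w = out[, 3])
}

# --- shared fixtures (built once per test run) -----------------------------

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

fx_geometry <- function() fixture("geometry", {
  build_spherical_geometry(geometry_config())
})

# 1D cable at the published parameters (speed + probe waveform)
fx_cable <- function() fixture("cable", {
  simulate_cable(table_params(), sigma_el = conductivity_model()$sigma_el,
                 varsigma = 0.8, dt = 0.01, t_end = 90)
})

# spherical-shell monodomain run with the fundus pacemaker
fx_shell <- function() fixture("shell", {
  p <- table_params()
  cond <- conductivity_model()
  tf <- assemble_tensor_field(function(r) spherical_fiber_direction(r, pi / 4),
                              cond$sigma_el, cond$sigma_et)
  shell <- generate_mesh(fx_geometry(), resolution = 0.012, dimension = 3,
                         compartments = "M")
  ops <- assemble_operators(shell, tf, cond$varsigma, p)
  cfg <- solver_config(dt = 0.02, t_end = 140, output_stride = 50)
  sol <- run_monodomain(shell, ops, p, list(fundus_pacemaker()), cfg)
  list(mesh = shell, sol = sol, params = p, cond = cond, tensor = tf)
})

# homogeneous conducting ball (fetal sphere, conductive) for the
# spherical-conductor oracles
fx_ball <- function(res = 0.019) fixture(paste0("ball", res), {
  generate_mesh(fx_geometry(), resolution = res, dimension = 3,
                compartments = "F")
})

fx_refractory <- function() fixture("refractory", {
  refractory_period(table_params())
})
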