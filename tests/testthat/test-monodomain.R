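test_that("stiffness null space is exactly the constants (no-flux)", {
  p <- table_params()
  # 1D cable
  ops1 <- assemble_operators(mesh_cable(0.1, 2e-3), 0.68, 0.8, p)
  expect_lt(max(abs(ops1$K %*% rep(1, nrow(ops1$K)))), 1e-12)
  # 3D shell with the oblique fiber tensor field
  sh <- fx_shell()
  ops3 <- assemble_operators(sh$mesh, sh$tensor, 0.8, p)
  expect_lt(max(abs(ops3$K %*% rep(1, nrow(sh$mesh$nodes)))), 1e-10)
  # linear field on the cable: interior stiffness action vanishes
  m <- mesh_cable(0.1, 2e-3)
  ops <- assemble_operators(m, 0.68, 0.8, p)
  v <- m$nodes[, 1] * 3
  resid <- as.numeric(ops$K %*% v)
  expect_lt(max(abs(resid[2:(length(v) - 1)])), 1e-10)
})

test_that("stiffness action approximates the second derivative at O(h^2)", {
  p <- table_params()
  sigma <- 0.5; fac <- 0.8 / 1.8
  errs <- vapply(c(2e-3, 1e-3, 5e-4), function(h) {
    m <- mesh_cable(0.1, h)
    ops <- assemble_operators(m, sigma, 0.8, p)
    x <- m$nodes[, 1]
    v <- sin(40 * x)
    # K v ~ -(fac sigma) v'' weighted by the lumped mass
    got <- as.numeric(ops$K %*% v) / ops$M
    expected <- fac * sigma * 40^2 * sin(40 * x)
    interior <- seq(5, length(x) - 4)
    max(abs(got[interior] - expected[interior]))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[2])
})

test_that("the IMEX step conserves the mass-weighted mean without reaction", {
  p <- table_params()
  m <- mesh_cable(0.1, 1e-3)
  ops <- assemble_operators(m, 0.68, 0.8, p)
  amcm <- p$a_m * p$c_m
  A <- Matrix::Diagonal(x = amcm * ops$M) + 0.05 * ops$K
  v <- -0.056 + 0.02 * exp(-((m$nodes[, 1] - 0.05) / 0.01)^2)  # a bump
  m0 <- sum(ops$M * v)
  r0 <- diff(range(v))
  for (i in 1:50) v <- as.numeric(Matrix::solve(A, amcm * ops$M * v))
  expect_equal(sum(ops$M * v), m0, tolerance = 1e-10)
  expect_lt(diff(range(v)), 0.5 * r0)   # diffusion flattens the bump
})

test_that("a quiescent sheet stays uniform and drifts to the fixed point", {
  p <- table_params()
  m <- mesh_cable(0.05, 2e-3)
  ops <- assemble_operators(m, 0.68, 0.8, p)
  sol <- run_monodomain(m, ops, p, list(),
                        solver_config(dt = 0.05, t_end = 400,
                                      output_stride = 100))
  v_end <- sol$v_m$values[, ncol(sol$v_m$values)]
  expect_lt(var(v_end), 1e-12)
  expect_equal(mean(v_end), equilibrium_state(p)$v_m, tolerance = 1e-4)
})

test_that("the cable front is a traveling wave with dt-converged speed", {
  sim <- fx_cable()
  expect_gt(sim$r_squared, 0.999)
  expect_gt(sim$speed, 0.004)  # an established, propagating front
  sim2 <- simulate_cable(table_params(), 0.68, 0.8, dt = 0.005, t_end = 40)
  expect_equal(sim2$speed, sim$speed, tolerance = 0.02)  # < 2% on halving dt
})

test_that("counter-propagating fronts annihilate without reflection", {
  p <- table_params()
  m <- mesh_cable(0.2, 1e-3)
  ops <- assemble_operators(m, 0.68, 0.8, p)
  both_ends <- pacemaker_spec(2, function(r, t) {
    if (t > 0.1) return(numeric(nrow(r)))
    as.numeric(r[, 1] <= 0.01 | r[, 1] >= 0.19)
  })
  sol <- run_monodomain(m, ops, p, list(both_ends),
                        solver_config(dt = 0.01, t_end = 60,
                                      output_stride = 50))
  v <- sol$v_m$values
  # both fronts excite the middle (collision), then everything repolarises
  mid <- which.min(abs(m$nodes[, 1] - 0.1))
  expect_gt(max(v[mid, ]), -0.03)
  expect_true(all(v[, ncol(v)] < -0.04))    # no surviving or reflected wave
})

test_that("a refractory cable blocks early restimulation but recovers later", {
  p <- table_params()
  m <- mesh_cable(0.12, 1e-3)
  ops <- assemble_operators(m, 0.68, 0.8, p)
  end_stim <- function(times) pacemaker_spec(2, function(r, t) {
    on <- any(t >= times & t <= times + 0.1)
    if (!on) return(numeric(nrow(r)))
    as.numeric(r[, 1] <= 0.01)
  })
  probe <- matrix(0.09, 1, 1)
  run_two <- function(gap) {
    sol <- run_monodomain(m, ops, p, list(end_stim(c(0.5, 0.5 + gap))),
                          solver_config(dt = 0.02, t_end = gap + 60,
                                        output_stride = 25))
    tr <- probe_trace(sol$v_m, probe)
    sum(diff(tr$probe1 > -0.04) == 1)  # number of distinct waves arriving
  }
  expect_equal(run_two(30), 1L)    # second stimulus falls in refractory
  expect_equal(run_two(300), 2L)   # after recovery the wave relaunches
})

test_that("instability is detected and reported when halvings are exhausted", {
  p <- table_params()
  m <- mesh_cable(0.05, 2e-3)
  ops <- assemble_operators(m, 0.68, 0.8, p)
  strong <- pacemaker_spec(5e4, function(r, t) as.numeric(r[, 1] <= 0.05))
  expect_error(
    run_monodomain(m, ops, p, list(strong),
                   solver_config(dt = 5, t_end = 50, max_dt_halvings = 0L)),
    "unstable")
})

test_that("operators demand SPD tensors and myometrial elements", {
  p <- table_params()
  m <- mesh_cable(0.05, 2e-3)
  expect_error(assemble_operators(m, -0.5, 0.8, p), "positive definite")
  m2 <- m; m2$elem_label <- rep(compartment_code("A"), nrow(m2$elems))
  expect_error(assemble_operators(m2, 0.68, 0.8, p), "labelled M")
})

test_that("the shell waveform keeps its shape across elevations", {
  sh <- fx_shell()
  th <- c(0.7, 1.3, 1.9)
  pts <- cbind(0.155 * sin(th), 0, 0.155 * cos(th))
  tr <- probe_trace(sh$sol$v_m, pts)
  metrics <- lapply(2:4, function(i)
    waveform_metrics(data.frame(t = tr$t, v = tr[[i]]),
                     resting = sh$params$v_mr))
  peaks <- vapply(metrics, function(m) m$peak_vm, numeric(1))
  durs <- vapply(metrics, function(m) m$duration_s, numeric(1))
  expect_lt(diff(range(peaks)), 2e-3)   # same peak within 2 mV
  expect_lt(diff(range(durs)), 5)       # same duration within 5 s
  # aligned traces correlate almost perfectly (identical shape up to shift)
  t_ref <- metrics[[1]]$t_up
  v1 <- approx(tr$t - t_ref, tr[[2]], seq(-5, 25, by = 0.5))$y
  v3 <- approx(tr$t - metrics[[3]]$t_up, tr[[4]], seq(-5, 25, by = 0.5))$y
  expect_gt(cor(v1, v3, use = "complete.obs"), 0.99)
})
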