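test_that("ionic current matches its defining cubic at landmark states", {
  p <- table_params()
  # cubic factor vanishes at v1
  expect_equal(ionic_current(list(v_m = p$v1, w = 0), p), 0)
  # at v2 only the -w term survives
  expect_equal(ionic_current(list(v_m = p$v2, w = 0.013), p), 0.013 / p$eps1)
  # direct arithmetic: v_m = -0.03, w = 0:
  # -(1/200) * 1e4 * (-0.01) * (-0.01) * (0.035) = -1.75e-4
  expect_equal(ionic_current(list(v_m = -0.03, w = 0), p), -1.75e-4)
})

test_that("ionic current is cubic in v_m and linear in w", {
  p <- table_params()
  # third finite difference of a cubic is constant; fourth vanishes
  h <- 1e-3
  v0 <- -0.04
  f <- vapply(0:4, function(k) ionic_current(list(v_m = v0 + k * h, w = 0), p),
              numeric(1))
  d4 <- f[1] - 4 * f[2] + 6 * f[3] - 4 * f[4] + f[5]
  expect_lt(abs(d4), 1e-12)
  d3 <- diff(diff(diff(f)))
  expect_equal(d3[1], d3[2], tolerance = 1e-9)
  # linearity in w
  s <- function(w) ionic_current(list(v_m = -0.03, w = w), p)
  expect_equal(s(0.2) - s(0.1), s(0.1) - s(0), tolerance = 1e-15)
})

test_that("recovery rate vanishes on its nullcline and at the resting state", {
  p <- table_params()
  v <- -0.033
  expect_equal(recovery_rate(list(v_m = v, w = (p$beta * v + p$delta) / p$gamma), p), 0)
  expect_equal(recovery_rate(list(v_m = -0.056, w = -0.04), p), 0)
  p0 <- table_params(beta = 0, delta = 0)
  expect_lt(recovery_rate(list(v_m = -0.05, w = 0.01), p0), 0)
})

test_that("the pacemaker stimulus has the published form and is additive", {
  p <- table_params()
  pm <- fundus_pacemaker()   # nu = 2, active band of the spherical fundus
  # outside the support
  expect_equal(stimulus_current(c(0, 0, 0.1), 0.05, list(pm), p), 0)
  expect_equal(stimulus_current(c(0.155, 0, 0.155), 0.2, list(pm), p), 0)
  # inside: nu/eps1 = 2/200 = 0.01
  pt <- c(0, 0, 0.155)
  expect_equal(stimulus_current(pt, 0.05, list(pm), p), 0.01)
  # two identical overlapping pacemakers double the current
  expect_equal(stimulus_current(pt, 0.05, list(pm, pm), p), 0.02)
})

test_that("the frozen-recovery cubic roots match an independent bracketing oracle", {
  p <- table_params()
  r <- nullcline_fixed_points(p)
  # independent oracle: sign-change bracketing + uniroot on the raw cubic
  f <- function(v) (v - p$v1) * (p$v2 - v) * (v - p$v3) -
    (p$beta * p$v_mr + p$delta) / (p$k * p$gamma)
  grid <- seq(-0.1, 0.02, by = 1e-4)
  sg <- which(f(grid[-1]) * f(grid[-length(grid)]) <= 0)
  oracle <- sort(vapply(sg, function(i)
    uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-14)$root, numeric(1)))[1:3]
  expect_equal(r, oracle, tolerance = 1e-10)
  expect_equal(r, c(-0.0600, -0.04851, -0.01649), tolerance = 1e-3)
  # residuals at machine scale
  expect_true(all(abs(f(r)) < 1e-12))
  # roots move continuously under a small delta perturbation
  r2 <- nullcline_fixed_points(table_params(delta = p$delta + 1e-6))
  expect_true(all(abs(r2 - r) < 1e-3))
})

test_that("degenerate parameterisations are rejected with the discriminant", {
  # enormous constant term pushes two roots complex
  expect_error(nullcline_fixed_points(table_params(delta = 0.5)),
               "discriminant")
  expect_error(resting_state(table_params(gamma = 1e-9, delta = 0)), NA)
})

test_that("the resting state follows the initial-condition formulas", {
  p <- table_params()
  r <- resting_state(p)
  expect_equal(r$v_m, -0.056)
  expect_equal(r$w, -0.04)    # (1 * (-0.056) + 0.052) / 0.1
  expect_equal(resting_state(table_params(beta = 0, delta = 0))$w, 0)
  expect_equal(resting_state(table_params(gamma = 1, delta = 0))$w, -0.056)
})

test_that("surface-to-volume ratio of the closed cylinder", {
  expect_equal(surface_to_volume(7e-6, 450e-6), 5.7587e5, tolerance = 1e-4)
  expect_equal(surface_to_volume(4, 2), 2)           # 1 + 1
  expect_equal(surface_to_volume(7e-6, 1e9), 4 / 7e-6, tolerance = 1e-6)
})

test_that("space-clamped integration agrees with the adaptive reference", {
  p <- table_params()
  drive <- pulse_drive(p, t_on = 1, duration = 0.02)
  ref <- oracle_integrate_0d(p, drive, 80)
  got <- integrate_space_clamped(p, drive, t_end = 80, dt = 0.002)
  # compare on the common grid
  gi <- approx(got$t, got$v_m, ref$t)$y
  expect_lt(max(abs(gi - ref$v_m), na.rm = TRUE), 2e-3)
  expect_equal(max(got$v_m), max(ref$v_m), tolerance = 1e-3)
})

test_that("without stimulus the membrane settles at the stable fixed point", {
  p <- table_params()
  tr <- integrate_space_clamped(p, NULL, t_end = 500, dt = 0.02,
                                output_stride = 50L)
  expect_lt(diff(range(tr$v_m)), 5e-3)  # stays within a few mV of rest
  ref <- oracle_integrate_0d(p, function(t) 0, 500,
                             times = c(0, 250, 500))
  expect_equal(tr$v_m[nrow(tr)], ref$v_m[3], tolerance = 1e-5)
  # the equilibrium sits within a few mV of the lowest frozen-recovery root
  eq <- equilibrium_state(p)
  expect_equal(tr$v_m[nrow(tr)], eq$v_m, tolerance = 1e-5)
  expect_lt(abs(eq$v_m - nullcline_fixed_points(p)[1]), 5e-3)
})

test_that("a brief suprathreshold pulse yields the plateau-and-undershoot shape", {
  p <- table_params()
  tr <- integrate_space_clamped(p, pulse_drive(p, 1, 0.02), t_end = 120,
                                dt = 0.01)
  expect_gt(max(tr$v_m), -0.03)              # depolarises past threshold
  expect_lt(min(tr$v_m), p$v_mr - 0.005)     # hyperpolarises below rest
  # plateau shape: spends tens of seconds above -30 mV
  expect_gt(sum(tr$v_m > -0.03) * 0.01, 15)
})

test_that("a second pulse 10 s after the first fails to re-excite", {
  p <- table_params()
  one <- integrate_space_clamped(p, pulse_drive(p, 1, 0.02), t_end = 80,
                                 dt = 0.01)
  two <- integrate_space_clamped(p, pulse_drive(p, c(1, 11), 0.02),
                                 t_end = 80, dt = 0.01)
  # the perturbed trajectory rejoins the single-pulse one: no second AP
  late <- one$t > 14
  expect_lt(max(abs(two$v_m[late] - one$v_m[late])), 5e-3)
  # whereas a pulse after full recovery does trigger a new depolarisation
  three <- integrate_space_clamped(p, pulse_drive(p, c(1, 400), 0.02),
                                   t_end = 440, dt = 0.01)
  expect_gt(max(three$v_m[three$t > 400]), -0.03)
})

test_that("trajectories stay bounded over 500 s and the step converges", {
  p <- table_params()
  tr <- integrate_space_clamped(p, pulse_drive(p, 1, 0.05), t_end = 500,
                                dt = 0.02, output_stride = 100L)
  expect_true(all(abs(tr$v_m) < 0.2))
  cv1 <- integration_convergence(p, pulse_drive(p, 1, 0.05), 40, dt = 0.02)
  cv2 <- integration_convergence(p, pulse_drive(p, 1, 0.05), 40, dt = 0.01)
  expect_lt(cv2$max_diff_v, cv1$max_diff_v)  # refining the step converges
  # divergence guard
  expect_error(integrate_space_clamped(p, pulse_drive(p, 0, 10, nu = 2000),
                                       t_end = 20, dt = 0.01, method = "rk4"),
               "reduce dt")
})
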