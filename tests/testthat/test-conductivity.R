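test_that("Archie's law extracellular conductivity", {
  expect_equal(archie_extracellular(0.5, 0, 4 / 3), 0.5)   # no inclusions
  expect_equal(archie_extracellular(0.5, 0.6, 4 / 3), 0.5 / 0.4^(4 / 3))
  expect_equal(archie_extracellular(0.5, 0.6, 4 / 3), 1.697, tolerance = 1e-3)
  expect_equal(archie_extracellular(0.3, 0.5, 1), 0.6)     # m = 1: 2 sigma
  expect_error(archie_extracellular(0.5, 1), "0 <= p < 1")
})

test_that("grid-model conductivities reproduce the published table", {
  se <- grid_conductivities(archie_extracellular(0.5, 0.6, 4 / 3),
                            myocyte_geometry(7e-6, 450e-6, 0.5e-6))
  expect_equal(round(unname(se["sigma_el"]), 2), 0.68)
  expect_equal(round(unname(se["sigma_et"]), 2), 0.22)
  # no cells: both revert to the medium value
  g0 <- suppressWarnings(myocyte_geometry(1e-12, 450e-6, 0.5e-6))
  se0 <- grid_conductivities(1.7, g0)
  expect_equal(unname(se0), c(1.7, 1.7), tolerance = 1e-4)
})

test_that("longitudinal exceeds transverse for any long-cylinder packing", {
  set.seed(3)
  for (i in 1:50) {
    d <- runif(1, 2e-6, 15e-6)
    l <- d * runif(1, 12, 100)
    de <- runif(1, 0.1e-6, 2e-6)
    se <- grid_conductivities(1, myocyte_geometry(d, l, de))
    expect_gt(se["sigma_el"], se["sigma_et"])
  }
})

test_that("anisotropy ratio: limits, admissible interval, and bound error", {
  p <- table_params()
  sigma_el <- 0.68
  # eps1 -> 0 drives the ratio to zero
  expect_lt(anisotropy_ratio(0.0115, table_params(eps1 = 1e-4), sigma_el), 1e-5)
  # continuity in eps1 on the admissible interval
  v1 <- anisotropy_ratio(0.006, table_params(eps1 = 100), sigma_el)
  v2 <- anisotropy_ratio(0.006, table_params(eps1 = 101), sigma_el)
  expect_gt(v2, v1)
  expect_lt(abs(v2 - v1) / v1, 0.05)
  # outside the admissible interval the calibration reports the bound
  bound <- eps1_upper_bound(0.0115, p, sigma_el)
  err <- tryCatch(anisotropy_ratio(0.0115, p, sigma_el), error = conditionMessage)
  expect_match(err, "admissible interval")
  expect_match(err, as.character(signif(bound, 6)), fixed = TRUE)
})

test_that("closed-form calibration matches the cable speed-matching oracle", {
  # the closed form assumes the recovery variable is frozen on the front
  # time-scale; validate in that regime (slow recovery) where both routes
  # must agree
  pf <- table_params(eps2 = 0.005)
  sigma_el <- 0.68
  target <- 0.006
  vs_closed <- anisotropy_ratio(target, pf, sigma_el)
  sim <- simulate_cable(pf, sigma_el, vs_closed, dt = 0.005,
                        resolution = 5e-4)
  expect_equal(sim$speed, target, tolerance = 0.1)   # speed match within 10%
  cal <- calibrate_varsigma_numeric(target, pf, sigma_el, dt = 0.005,
                                    resolution = 5e-4)
  expect_equal(cal$varsigma, vs_closed, tolerance = 0.1)
})

test_that("tensor assembly is cylindrically symmetric and equivariant", {
  tf <- assemble_tensor_field(function(r) {
    r <- matrix(r, ncol = 3); matrix(rep(c(0, 0, 1), each = nrow(r)), ncol = 3)
  }, sigma_l = 0.68, sigma_t = 0.22)
  G <- tf(c(0.1, 0, 0))[, , 1]
  expect_equal(G, diag(c(0.22, 0.22, 0.68)))
  # zero fiber: isotropic point
  tf0 <- assemble_tensor_field(function(r) matrix(0, nrow(matrix(r, ncol = 3)), 3),
                               0.68, 0.22)
  expect_equal(tf0(c(1, 2, 3))[, , 1], 0.22 * diag(3))
  # random unit fiber: eigenvalues (t, t, l)
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    tfa <- assemble_tensor_field(function(r) matrix(a, nrow(matrix(r, ncol = 3)),
                                                    3, byrow = TRUE), 0.68, 0.22)
    ev <- eigen(tfa(c(0, 0, 0))[, , 1], symmetric = TRUE)$values
    expect_equal(sort(ev), c(0.22, 0.22, 0.68), tolerance = 1e-12)
  }
  # rotation equivariance: G(R a) = R G(a) R^T
  for (i in 1:10) {
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    qr_ <- qr(matrix(rnorm(9), 3)); R <- qr.Q(qr_)
    mk <- function(vec) assemble_tensor_field(function(r)
      matrix(vec, nrow(matrix(r, ncol = 3)), 3, byrow = TRUE), 0.68, 0.22)
    G1 <- mk(drop(R %*% a))(c(0, 0, 0))[, , 1]
    G2 <- R %*% mk(a)(c(0, 0, 0))[, , 1] %*% t(R)
    expect_equal(G1, G2, tolerance = 1e-12)
  }
  # non-unit nonzero fiber rejected
  bad <- assemble_tensor_field(function(r)
    matrix(0.5, nrow(matrix(r, ncol = 3)), 3), 0.68, 0.22)
  expect_error(bad(c(1, 0, 0)), "unit or zero")
})

test_that("equal anisotropy: G_i = varsigma * G_e pointwise", {
  cm <- conductivity_model()
  fib <- function(r) spherical_fiber_direction(r, pi / 4)
  Ge <- assemble_tensor_field(fib, cm$sigma_el, cm$sigma_et)
  Gi <- assemble_tensor_field(fib, cm$sigma_il, cm$sigma_it)
  set.seed(9)
  pts <- matrix(rnorm(30), ncol = 3)
  expect_equal(Gi(pts), cm$varsigma * Ge(pts), tolerance = 1e-12)
})

test_that("the myocyte-table pipeline reproduces the published conductivities", {
  cm <- conductivity_model(sigma_M = 0.5, p = 0.6, m = 4 / 3,
                           geom = myocyte_geometry(7e-6, 450e-6, 0.5e-6),
                           varsigma = 0.8)
  expect_equal(round(cm$sigma_el, 2), 0.68)
  expect_equal(round(cm$sigma_et, 2), 0.22)
  expect_equal(cm$sigma_il, 0.8 * cm$sigma_el)
  expect_equal(cm$sigma_it, 0.8 * cm$sigma_et)
  expect_equal(cm$G_U, 1.74)
})
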