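cond_unit <- function() conductivity_model(G_F = 1)

test_that("a spatially constant v_m produces zero potential", {
  g <- fx_geometry()
  m <- generate_mesh(g, 0.03, 3, compartments = c("U", "M", "A"))
  vm <- rep(-0.056, nrow(m$nodes))
  sol <- solve_potentials(m, vm, conductivity_model())
  expect_lt(max(abs(sol$phi), na.rm = TRUE), 1e-12)
})

test_that("the potential is linear in the source and gauge-consistent", {
  g <- fx_geometry()
  m <- generate_mesh(g, 0.03, 3, compartments = c("U", "M", "A"))
  subM <- uterowave:::submesh(m, "M")
  vm <- rep(-0.056, nrow(m$nodes))
  depol <- m$nodes[, 3] > 0.1 &
    sqrt(rowSums(m$nodes^2)) >= 0.15 - 1e-9
  vm[depol] <- -0.016
  s1 <- solve_potentials(m, vm, conductivity_model())
  s2 <- solve_potentials(m, -0.056 + 2 * (vm + 0.056), conductivity_model())
  ok <- !is.na(s1$phi)
  expect_equal(s2$phi[ok], 2 * s1$phi[ok], tolerance = 1e-10)
  # gauge: zero mean over the abdominal surface nodes
  da <- unique(as.integer(m$facets[m$facet_label == boundary_code("dA"), ]))
  expect_lt(abs(mean(s1$phi[da])), 1e-13)
  expect_gt(max(abs(s1$phi), na.rm = TRUE), 0)   # nontrivial solution
})

test_that("the assembled operator is symmetric before gauge fixing", {
  g <- fx_geometry()
  m <- generate_mesh(g, 0.035, 3, compartments = c("U", "M", "A"))
  pre <- uterowave:::prepare_potential_solver(m, conductivity_model(), NULL, 0)
  expect_lt(Matrix::norm(pre$K - Matrix::t(pre$K), "M"), 1e-14)
})

test_that("dipole surface potentials match the analytic sphere series", {
  # insulated homogeneous sphere; subtraction discretisation of the dipole
  ball <- fx_ball()
  b0 <- 0.06; pm <- 1e-8
  rad <- sqrt(rowSums(ball$nodes^2))
  surf <- which(abs(rad - 0.12) < 1e-9)
  th <- acos(pmin(1, pmax(-1, ball$nodes[surf, 3] / rad[surf])))
  ph <- atan2(ball$nodes[surf, 2], ball$nodes[surf, 1])
  for (case in c("radial", "tangential")) {
    mom <- if (case == "radial") c(0, 0, pm) else c(pm, 0, 0)
    sol <- solve_dipole_potential(ball, c(0, 0, b0), mom, cond_unit(),
                                  lambda = 1)
    ana <- vapply(seq_along(surf), function(i)
      oracle_dipole_sphere_surface(0.12, 1, b0,
                                   if (case == "radial") pm else 0,
                                   if (case == "tangential") pm else 0,
                                   th[i], ph[i]), numeric(1))
    fem <- sol$phi[surf] - mean(sol$phi[surf])
    ana <- ana - mean(ana)
    rel <- sqrt(mean((fem - ana)^2)) / sqrt(mean(ana^2))
    expect_lt(rel, 0.02)
  }
})

test_that("refinement reduces the dipole-oracle error monotonically", {
  b0 <- 0.06; pm <- 1e-8
  errs <- vapply(c(0.03, 0.024, 0.019), function(res) {
    ball <- fx_ball(res)
    sol <- solve_dipole_potential(ball, c(0, 0, b0), c(0, 0, pm), cond_unit(),
                                  lambda = 1)
    rad <- sqrt(rowSums(ball$nodes^2))
    surf <- which(abs(rad - 0.12) < 1e-9)
    th <- acos(pmin(1, pmax(-1, ball$nodes[surf, 3] / rad[surf])))
    ana <- vapply(seq_along(surf), function(i)
      oracle_dipole_sphere_surface(0.12, 1, b0, pm, 0, th[i], 0), numeric(1))
    fem <- sol$phi[surf] - mean(sol$phi[surf]); ana <- ana - mean(ana)
    sqrt(mean((fem - ana)^2)) / sqrt(mean(ana^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("series solves are snapshot-wise independent and reproducible", {
  g <- fx_geometry()
  m <- generate_mesh(g, 0.035, 3, compartments = c("U", "M", "A"))
  subM <- uterowave:::submesh(m, "M")
  vm <- rep(-0.056, nrow(subM$mesh$nodes))
  vm[subM$mesh$nodes[, 3] > 0.1] <- -0.02
  V <- matrix(vm, length(vm), 3)
  ser <- field_series(c(0, 1, 2), V, subM$mesh, "v_m", "V")
  lifted <- matrix(0, nrow(m$nodes), 3)
  lifted[subM$node_map, ] <- V
  phi <- solve_potential_series(m, field_series(c(0, 1, 2), lifted, m),
                                conductivity_model())
  expect_equal(phi$values[, 1], phi$values[, 2])   # identical inputs
  expect_equal(phi$values[, 2], phi$values[, 3])
})

test_that("the vernix switch changes the abdominal potential measurably", {
  g <- fx_geometry()
  m <- generate_mesh(g, 0.025, 3, compartments = c("F", "U", "M", "A"))
  subM <- uterowave:::submesh(m, "M")
  vm <- rep(-0.056, nrow(m$nodes))
  onM <- sqrt(rowSums(m$nodes^2)) >= 0.15 - 1e-9
  vm[onM & m$nodes[, 3] > 0.1] <- -0.016
  s0 <- solve_potentials(m, vm, conductivity_model(), lambda = 0)
  s1 <- solve_potentials(m, vm, conductivity_model(), lambda = 1)
  da <- unique(as.integer(m$facets[m$facet_label == boundary_code("dA"), ]))
  rel <- sqrt(sum((s0$phi[da] - s1$phi[da])^2) / sum(s0$phi[da]^2))
  expect_gt(rel, 0.005)
  # with lambda = 0 the fetal interior is excluded from the solve
  rF <- sqrt(rowSums(m$nodes^2)) < 0.12 - 1e-9
  expect_true(all(is.na(s0$phi[rF])))
  expect_false(anyNA(s1$phi))
})
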