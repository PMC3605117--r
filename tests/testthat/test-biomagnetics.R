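test_that("a discretised current loop reproduces the textbook centre field", {
  R <- 0.05; I <- 2; nseg <- 1000
  th <- seq(0, 2 * pi, length.out = nseg + 1)[-1]
  cur <- current_field(points = cbind(R * cos(th), R * sin(th), 0),
                       J = cbind(-sin(th), cos(th), 0),
                       volumes = rep(I * 2 * pi * R / nseg, nseg))
  B <- magnetic_field(cur, c(0, 0, 0))
  expect_equal(B[1, 3], 4e-7 * pi * I / (2 * R), tolerance = 0.01)
  expect_lt(max(abs(B[1, 1:2])), 1e-18)
  # linearity: doubling the current doubles the field
  cur2 <- current_field(cur$points, cur$J, 2 * cur$volumes)
  expect_equal(magnetic_field(cur2, c(0, 0, 0.02)),
               2 * magnetic_field(cur, c(0, 0, 0.02)), tolerance = 1e-12)
})

test_that("impressed currents vanish for uniform v_m and rotate with the tensors", {
  p <- table_params()
  m <- fx_shell()$mesh
  tf <- fx_shell()$tensor
  Js0 <- impressed_current(m, rep(-0.056, nrow(m$nodes)), tf, 0.8)
  expect_lt(max(abs(Js0$J)), 1e-12)
  # 1D: J_s = -sigma_il dv/dx against a linear profile
  cab <- mesh_cable(0.1, 2e-3)
  v <- -0.056 + 0.1 * cab$nodes[, 1]
  Js <- impressed_current(cab, v, 0.68, 0.8)
  expect_equal(unique(round(Js$J[, 1], 9)), round(-0.8 * 0.68 * 0.1, 9))
  # rotation equivariance on a small synthetic patch
  qr_ <- qr(matrix(c(0.1, 0.4, -0.3, 0.9, 0.2, 0.1, -0.2, 0.5, 0.8), 3))
  R <- qr.Q(qr_)
  a <- c(0, 0, 1)
  mkJ <- function(fib, grad_v) {
    # single-tet mesh with prescribed nodal values
    nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) * 0.01
    mm <- uterowave:::new_mesh(nodes, matrix(1:4, 1), compartment_code("M"),
                               NULL, integer(0), 3L)
    tfx <- assemble_tensor_field(function(r)
      matrix(fib, nrow(uterowave:::as_points3(r)), 3, byrow = TRUE), 0.68, 0.22)
    v <- drop(nodes %*% grad_v)
    impressed_current(mm, v, tfx, 0.8)$J[1, ]
  }
  gv <- c(2, -1, 0.5)
  J1 <- mkJ(drop(R %*% a), drop(R %*% gv))
  J2 <- drop(R %*% mkJ(a, gv))
  expect_equal(J1, J2, tolerance = 1e-10)
})

test_that("total current reduces to its parts and is solenoidal", {
  g <- fx_geometry()
  m <- generate_mesh(g, 0.03, 3, compartments = c("U", "M", "A"))
  cm <- conductivity_model()
  # zero fields give zero current
  z <- total_current(m, rep(0, nrow(m$nodes)), rep(0, nrow(m$nodes)), cm)
  expect_lt(max(abs(z$J)), 1e-15)
  # J minus the ohmic part equals J_s on the myometrium
  vm <- rep(-0.056, nrow(m$nodes))
  vm[m$nodes[, 3] > 0.12 & sqrt(rowSums(m$nodes^2)) >= 0.15 - 1e-9] <- -0.02
  sol <- solve_potentials(m, vm, cm)
  tot <- total_current(m, vm, sol$phi, cm)
  tfe <- isotropic_tensor_field(cm$sigma_et)
  Js <- impressed_current(m, vm, tfe, cm$varsigma)
  phi0 <- ifelse(is.na(sol$phi), 0, sol$phi)
  gp <- uterowave:::field_gradient(m, phi0)
  Gvc <- uterowave:::volume_conductor_tensors(m, cm, tfe, 0)
  ohm <- -vapply(1:3, function(a)
    rowSums(vapply(1:3, function(b) Gvc[a, b, ] * gp[, b],
                   numeric(nrow(m$elems)))), numeric(nrow(m$elems)))
  onM <- m$elem_label == compartment_code("M")
  expect_equal(tot$J[onM, ], (Js$J + ohm)[onM, ], tolerance = 1e-12)
  # quasi-static solenoidality: the discrete weak divergence (residual of
  # the potential solve) vanishes at interior nodes
  pre <- uterowave:::prepare_potential_solver(m, cm, NULL, 0)
  resid <- as.numeric(pre$K %*% phi0 - sol$rhs)
  act <- pre$active
  expect_lt(max(abs(resid[act])) / max(abs(sol$rhs)), 1e-8)
})

test_that("a radial source in a spherical conductor is magnetically silent", {
  ball <- fx_ball(0.015)
  cm <- conductivity_model(G_F = 1)
  ctr <- element_centroids(ball); vols <- element_volumes(ball)
  rc <- c(0, 0, 0.06); a_blob <- 0.025; A <- 1e-4
  bump <- function(d) ifelse(d < a_blob, (1 - (d / a_blob)^2)^2, 0)
  sph <- uterowave:::icosphere(3)
  obs <- sph$vertices * 0.2
  B_of <- function(case) {
    J_fun <- function(r) {
      d <- sqrt(rowSums(sweep(r, 2, rc)^2)); f <- A * bump(d)
      if (case == "radial") {
        rn <- sqrt(rowSums(r^2)); rn[rn == 0] <- 1
        r / rn * f
      } else cbind(f, 0, 0)
    }
    sol <- solve_primary_potential(ball, J_fun, cm, lambda = 1)
    gphi <- uterowave:::field_gradient(ball, sol$phi)
    list(B = magnetic_field(current_field(ctr, J_fun(ctr) - gphi, vols, ball),
                            obs),
         p_eff = colSums(J_fun(ctr) * vols))
  }
  rad <- B_of("radial"); tan <- B_of("tangential")
  u <- obs / 0.2
  Bn_rad <- rowSums(rad$B * u)
  Bs <- t(apply(obs, 1, function(r) oracle_sarvas(tan$p_eff, rc, r)))
  Bn_tan_ref <- rowSums(Bs * u)
  # silent source: normal field below 1% of the tangential reference
  expect_lt(max(abs(Bn_rad)), 0.01 * max(abs(Bn_tan_ref)))
  # tangential source agrees with the spherical-conductor closed form
  expect_lt(sqrt(sum((tan$B - Bs)^2)) / sqrt(sum(Bs^2)), 0.05)
})

test_that("net magnetic flux through a closed surface vanishes", {
  ball <- fx_ball(0.019)
  cm <- conductivity_model(G_F = 1)
  ctr <- element_centroids(ball); vols <- element_volumes(ball)
  rc <- c(0, 0, 0.06); a_blob <- 0.025
  bump <- function(d) ifelse(d < a_blob, (1 - (d / a_blob)^2)^2, 0)
  J_fun <- function(r) {
    d <- sqrt(rowSums(sweep(r, 2, rc)^2)); cbind(1e-4 * bump(d), 0, 0)
  }
  sol <- solve_primary_potential(ball, J_fun, cm, lambda = 1)
  gphi <- uterowave:::field_gradient(ball, sol$phi)
  cur <- current_field(ctr, J_fun(ctr) - gphi, vols, ball)
  sph <- uterowave:::icosphere(3)
  fctr <- 0.2 * (sph$vertices[sph$faces[, 1], ] +
                 sph$vertices[sph$faces[, 2], ] +
                 sph$vertices[sph$faces[, 3], ]) / 3
  fctr <- 0.2 * fctr / sqrt(rowSums(fctr^2)) # project back on the sphere
  e1 <- 0.2 * sph$vertices[sph$faces[, 2], ] - 0.2 * sph$vertices[sph$faces[, 1], ]
  e2 <- 0.2 * sph$vertices[sph$faces[, 3], ] - 0.2 * sph$vertices[sph$faces[, 1], ]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / 2
  sgn <- sign(rowSums(nrm * fctr)); nrm <- nrm * sgn
  B <- magnetic_field(cur, fctr)
  net <- sum(rowSums(B * nrm))
  gross <- sum(abs(rowSums(B * nrm)))
  expect_lt(abs(net) / gross, 1e-3)
})

test_that("the MMG projection extracts the normal component", {
  sens <- sensor_array(rbind(c(0.2, 0, 0), c(0, 0.2, 0)),
                       rbind(c(1, 0, 0), c(0, 1, 0)))
  B <- rbind(c(0, 1e-12, 0), c(0, 1e-12, 0))
  expect_equal(mmg_projection(B, sens), c(0, 1e-12))
  expect_error(sensor_array(c(0.2, 0, 0), c(2, 0, 0)), "unit length")
})

test_that("oblique fibers rotate the impressed current off the propagation axis", {
  sh <- fx_shell()
  # mid-propagation snapshot: front on the shell
  j <- which.min(abs(sh$sol$v_m$times - 40))
  v <- sh$sol$v_m$values[, j]
  Js <- impressed_current(sh$mesh, v, sh$tensor, sh$cond$varsigma)
  gv <- uterowave:::field_gradient(sh$mesh, v)
  nJ <- sqrt(rowSums(Js$J^2)); ng <- sqrt(rowSums(gv^2))
  sel <- nJ > 0.05 * max(nJ) & ng > 0.05 * max(ng)
  cosang <- abs(rowSums(Js$J[sel, ] * gv[sel, ])) / (nJ[sel] * ng[sel])
  ang <- acos(pmin(1, cosang)) * 180 / pi
  expect_gt(median(ang), 5)
})
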