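# ---------------------------------------------------------------------------
# Impressed and total current densities, and the abdominal magnetic field by
# Biot-Savart quadrature over element currents. Under quasi-statics this is
# equivalent to solving curl(B/mu0) = J with continuity conditions; the
# quadrature avoids meshing the surrounding air.
# ---------------------------------------------------------------------------

MU0 <- 4e-7 * pi

#' Sensor array on or near the abdominal surface
#'
#' @param positions n x 3 sensor positions (m)
#' @param normals n x 3 unit outward normals
#' @param ids sensor identifiers (default 1..n)
#' @return a `sensor_array` object
#' @export
sensor_array <- function(positions, normals, ids = NULL) {
  positions <- as_points3(positions); normals <- as_points3(normals)
  if (nrow(positions) != nrow(normals))
    stop("sensor_array: positions and normals must have equal rows")
  nn <- sqrt(rowSums(normals^2))
  if (any(abs(nn - 1) > 1e-6))
    stop("sensor_array: normals must be unit length (max deviation ",
         signif(max(abs(nn - 1)), 3), ")")
  if (is.null(ids)) ids <- seq_len(nrow(positions))
  structure(list(positions = positions, normals = normals, ids = ids),
            class = "sensor_array")
}

#' Spherical-cap sensor array over the abdominal surface
#'
#' Sensors on the abdominal sphere (radius and centre from the geometry),
#' restricted to directions within `cap_angle` of `cap_axis` (the ventral
#' surface a sensor array faces), with outward normals radial from the
#' abdominal centre.
#'
#' @param geometry a `uw_geometry`
#' @param nsub icosphere subdivision controlling the sensor count
#' @param cap_axis unit direction of the cap centre
#' @param cap_angle half-opening angle (rad); `pi` gives the whole sphere
#' @param offset radial offset above the surface (m)
#' @return a [sensor_array()]
#' @export
abdominal_sensor_array <- function(geometry, nsub = 3L,
                                   cap_axis = c(1, 0, 0), cap_angle = pi,
                                   offset = 0) {
  cfg <- geometry$config
  sph <- icosphere(nsub)
  u <- sph$vertices
  cap_axis <- cap_axis / sqrt(sum(cap_axis^2))
  keep <- drop(u %*% cap_axis) >= cos(cap_angle)
  u <- u[keep, , drop = FALSE]
  pos <- sweep(u * (cfg$r_abdomen + offset), 2, cfg$abdomen_offset, "+")
  sensor_array(pos, u)
}

#' Read/write sensor layouts as CSV (id, x, y, z, nx, ny, nz)
#' @param file path
#' @return a [sensor_array()]
#' @export
read_sensor_csv <- function(file) {
  df <- read.csv(file)
  sensor_array(unname(as.matrix(df[, c("x", "y", "z")])),
               unname(as.matrix(df[, c("nx", "ny", "nz")])), ids = df$id)
}

#' @rdname read_sensor_csv
#' @param sensors a [sensor_array()]
#' @export
write_sensor_csv <- function(sensors, file) {
  df <- data.frame(id = sensors$ids,
                   x = sensors$positions[, 1], y = sensors$positions[, 2],
                   z = sensors$positions[, 3],
                   nx = sensors$normals[, 1], ny = sensors$normals[, 2],
                   nz = sensors$normals[, 3])
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Element-wise current density container
#'
#' Bundles quadrature points (element midpoints), current-density vectors
#' and element volumes for [magnetic_field()]. Usually produced by
#' [impressed_current()] or [total_current()]; may be built directly for
#' synthetic sources (e.g. discretised current loops, where `J * volumes`
#' plays the role of `I dl`).
#'
#' @param points n x 3 quadrature points (m)
#' @param J n x 3 current densities (A/m^2)
#' @param volumes element volumes (m^3)
#' @param mesh optional generating mesh (enables near-sensor refinement)
#' @return a `current_field` object
#' @export
current_field <- function(points, J, volumes, mesh = NULL) {
  structure(list(points = as_points3(points), J = as_points3(J),
                 volumes = volumes, mesh = mesh), class = "current_field")
}

#' Impressed (source) current density
#'
#' \eqn{J_s = -G_i'\nabla v_m} per element, nonzero only where the
#' transmembrane potential has a spatial gradient (depolarisation or
#' repolarisation fronts).
#'
#' @param mesh myometrial mesh (or full mesh whose M elements are used)
#' @param v_m nodal transmembrane potential on `mesh`
#' @param tensor_field extracellular tensor field (or scalar sigma_el for a
#'   cable); the intracellular tensor is `varsigma` times it
#' @param varsigma equal-anisotropy ratio
#' @return a `current_field` with element midpoints, J_s vectors (A/m^2)
#'   padded to 3 components, and element volumes
#' @export
impressed_current <- function(mesh, v_m, tensor_field, varsigma) {
  d <- mesh$dim
  grads <- p1_gradients(mesh)
  onM <- mesh$elem_label == COMPARTMENT_CODES["M"]
  gv <- field_gradient(mesh, v_m, grads)
  G <- element_tensors(mesh, tensor_field) * varsigma
  J <- matrix(0, nrow(mesh$elems), d)
  for (a in seq_len(d)) for (b in seq_len(d))
    J[, a] <- J[, a] - G[a, b, ] * gv[, b]
  J[!onM, ] <- 0
  current_field(element_centroids(mesh), J, element_volumes(mesh), mesh)
}

#' Total current density over all conductive compartments
#'
#' On M: \eqn{J = -G_i'\nabla v_m - G_M'\nabla\phi_e} with
#' \eqn{G_M' = (1+\varsigma)G_e'}; on A, U (and F when `lambda != 0`):
#' \eqn{J = -G\nabla\phi}. Elements excluded from the potential solve carry
#' zero current.
#'
#' @param mesh full volume-conductor mesh
#' @param v_m nodal transmembrane potential (full-mesh or M-submesh layout)
#' @param phi nodal potential from [solve_potentials()] (NA allowed on
#'   excluded nodes)
#' @param conductivity a [conductivity_model()]
#' @param tensor_field optional extracellular tensor field on M
#' @param lambda vernix switch
#' @return a `current_field` (A/m^2)
#' @export
total_current <- function(mesh, v_m, phi, conductivity, tensor_field = NULL,
                          lambda = 0) {
  d <- mesh$dim
  grads <- p1_gradients(mesh)
  lab <- mesh$elem_label
  n <- nrow(mesh$nodes)
  vfull <- numeric(n)
  if (length(v_m) == n) vfull <- as.numeric(v_m)
  else {
    elM_nodes <- sort(unique(as.integer(mesh$elems[lab == COMPARTMENT_CODES["M"], ])))
    if (length(v_m) != length(elM_nodes))
      stop("total_current: v_m layout does not match the mesh")
    vfull[elM_nodes] <- as.numeric(v_m)
  }
  phi0 <- ifelse(is.na(phi), 0, phi)
  gv <- field_gradient(mesh, vfull, grads)
  gp <- field_gradient(mesh, phi0, grads)
  if (is.null(tensor_field))
    tensor_field <- isotropic_tensor_field(conductivity$sigma_et)
  Gvc <- volume_conductor_tensors(mesh, conductivity, tensor_field, lambda)
  Ge <- element_tensors(mesh, tensor_field)
  J <- matrix(0, nrow(mesh$elems), d)
  onM <- lab == COMPARTMENT_CODES["M"]
  vs <- conductivity$varsigma
  for (a in seq_len(d)) for (b in seq_len(d)) {
    J[, a] <- J[, a] - Gvc[a, b, ] * gp[, b]
    J[onM, a] <- J[onM, a] - vs * Ge[a, b, onM] * gv[onM, b]
  }
  if (lambda == 0) J[lab == COMPARTMENT_CODES["F"], ] <- 0
  current_field(element_centroids(mesh), J, element_volumes(mesh), mesh)
}

#' Magnetic field by Biot-Savart quadrature
#'
#' \deqn{B(r) = \frac{\mu_0}{4\pi}\sum_e J_e \times \frac{r - r_e}{\|r-r_e\|^3}\, V_e,}
#' with single-point (element midpoint) quadrature, optionally refined to a
#' four-point rule for elements closer to an observation point than
#' `refine_within` element diameters. Observation points falling inside an
#' element (kernel singularity) cause that element to be excluded with a
#' warning.
#'
#' @param current a `current_field` (from [impressed_current()],
#'   [total_current()], or built directly) — or a list with `points`
#'   (n x 3), `J` (n x 3, A/m^2) and `volumes`
#' @param observation_points m x 3 matrix (m)
#' @param refine_within refine quadrature for elements within this many
#'   element diameters of a sensor (0 disables)
#' @return m x 3 matrix of B (tesla)
#' @export
magnetic_field <- function(current, observation_points, refine_within = 2) {
  obs <- as_points3(observation_points)
  pts <- current$points; J <- current$J; vol <- current$volumes
  pts3 <- as_points3(pts); J3 <- as_points3(J)
  # element size scales: `size` (volume-based) guards the kernel
  # singularity, `diam` (resolution-based) controls near-sensor refinement
  dpow <- if (!is.null(current$mesh)) current$mesh$dim else 3L
  size <- vol^(1 / dpow)
  diam <- if (!is.null(current$mesh) && is.finite(current$mesh$resolution))
    rep(current$mesh$resolution, length(vol)) else size
  B <- matrix(0, nrow(obs), 3)
  excluded <- 0L
  # optional refined points for near elements: 4-point barycentric rule
  refine_pts <- NULL
  if (refine_within > 0 && !is.null(current$mesh) && current$mesh$dim == 3L) {
    mesh <- current$mesh
    vert <- lapply(1:4, function(j) mesh$nodes[mesh$elems[, j], , drop = FALSE])
    a <- 0.5854102; b <- 0.1381966  # standard 4-point tet rule
    refine_pts <- lapply(1:4, function(k) {
      w <- rep(b, 4); w[k] <- a
      w[1] * vert[[1]] + w[2] * vert[[2]] + w[3] * vert[[3]] + w[4] * vert[[4]]
    })
  }
  for (i in seq_len(nrow(obs))) {
    dx <- sweep(pts3, 2, obs[i, ], "-")   # r_e - r
    dist <- sqrt(rowSums(dx^2))
    inside <- dist < 0.4 * size
    if (any(inside)) excluded <- excluded + sum(inside)
    near <- if (is.null(refine_pts)) rep(FALSE, length(dist))
            else !inside & dist < refine_within * diam
    far <- !inside & !near
    acc <- c(0, 0, 0)
    add_contrib <- function(sel, points_sel, weight) {
      if (!any(sel)) return(invisible())
      dd <- sweep(points_sel, 2, obs[i, ], "-")  # r_e - r
      dv <- sqrt(rowSums(dd^2))
      f <- weight[sel] / dv^3
      # B += J x (r - r_e)/|..|^3 = -J x (r_e - r)/|..|^3
      Jx <- J3[sel, , drop = FALSE]
      cr <- cbind(Jx[, 2] * dd[, 3] - Jx[, 3] * dd[, 2],
                  Jx[, 3] * dd[, 1] - Jx[, 1] * dd[, 3],
                  Jx[, 1] * dd[, 2] - Jx[, 2] * dd[, 1])
      acc <<- acc - colSums(cr * f)
    }
    add_contrib(far, pts3[far, , drop = FALSE], vol)
    if (!is.null(refine_pts) && any(near)) {
      for (k in 1:4)
        add_contrib(near, refine_pts[[k]][near, , drop = FALSE], vol / 4)
    }
    B[i, ] <- acc * MU0 / (4 * pi)
  }
  if (excluded > 0L)
    warning("magnetic_field: ", excluded,
            " element(s) excluded (observation point inside)")
  B
}

#' Project the magnetic field on the sensor normals (MMG signal)
#'
#' @param B m x 3 field at the sensors (T)
#' @param sensors a [sensor_array()] with m sensors
#' @return numeric vector \eqn{B_{MMG} = \langle B, \hat n_A\rangle}
#' @export
mmg_projection <- function(B, sensors) {
  B <- as_points3(B)
  if (nrow(B) != nrow(sensors$positions))
    stop("mmg_projection: B rows must match the sensor count")
  rowSums(B * sensors$normals)
}
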