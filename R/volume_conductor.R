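# ---------------------------------------------------------------------------
# Quasi-static volume-conductor solves: given the transmembrane potential on
# the myometrium, find the interstitial potential in M and the passive
# potentials in U and A (and F when the fetal surface is conductive).
# A single conforming discretisation with piecewise conductivity tensors
# imposes potential continuity across interfaces by construction; interface
# flux continuity holds weakly.
# ---------------------------------------------------------------------------

# per-element conductivity tensors of the full volume conductor
volume_conductor_tensors <- function(mesh, conductivity, tensor_field = NULL,
                                     lambda = 0) {
  d <- mesh$dim; ne <- nrow(mesh$elems)
  G <- array(0, c(d, d, ne))
  lab <- mesh$elem_label
  iso <- function(els, sigma) {
    for (k in seq_len(d)) G[k, k, els] <<- sigma
  }
  iso(which(lab == COMPARTMENT_CODES["A"]), conductivity$G_A)
  iso(which(lab == COMPARTMENT_CODES["U"]), conductivity$G_U)
  iso(which(lab == COMPARTMENT_CODES["F"]), conductivity$G_F)
  elM <- which(lab == COMPARTMENT_CODES["M"])
  if (length(elM) > 0L) {
    vs <- conductivity$varsigma
    if (is.null(tensor_field))
      tensor_field <- isotropic_tensor_field(conductivity$sigma_et)
    Ge <- element_tensors(mesh, tensor_field)
    # bulk myometrium tensor G_M' = (1 + varsigma) G_e'
    G[, , elM] <- (1 + vs) * Ge[, , elM, drop = FALSE]
  }
  G
}

# solve K phi = b with pure Neumann gauge handling; returns full-length phi
# with NA at excluded nodes
solve_neumann <- function(K, b, active, gauge_nodes = NULL) {
  n <- length(b)
  act <- which(active)
  # compatibility: the RHS must be orthogonal to constants
  s <- sum(b[act])
  scale <- max(abs(b[act]), 1e-300)
  if (abs(s) > 1e-8 * scale * length(act))
    b[act] <- b[act] - s / length(act)
  pin <- act[1]
  keep <- setdiff(act, pin)
  Kr <- K[keep, keep, drop = FALSE]
  phi <- rep(NA_real_, n)
  phi[pin] <- 0
  sol <- Matrix::solve(Matrix::Cholesky(Matrix::forceSymmetric(Kr), LDL = FALSE,
                                        perm = TRUE),
                       b[keep])
  phi[keep] <- as.numeric(sol)
  if (is.null(gauge_nodes) || length(gauge_nodes) == 0L) gauge_nodes <- act
  phi - mean(phi[gauge_nodes], na.rm = TRUE)
}

#' Solve the interface problem for the volume-conductor potentials
#'
#' Given a transmembrane-potential snapshot \eqn{v_m} on the myometrial
#' nodes, solves the elliptic problem
#' \deqn{\nabla\cdot(G\nabla\phi) = \nabla\cdot J_s, \qquad
#'       J_s = -G_i'\nabla v_m \; \mathrm{in}\; M,}
#' with \eqn{G = (1+\varsigma)G_e'} in M, the isotropic compartment
#' conductivities in A, U (and F when `lambda != 0`), continuity of the
#' potential across interfaces (conforming discretisation), no flux through
#' the abdominal surface, and an insulated fetal surface when `lambda = 0`
#' (fetal elements are then excluded from the solve). The potential is
#' gauged to zero mean over the abdominal-surface nodes (falling back to the
#' global mean when the mesh has no `dA` facets).
#'
#' @param mesh full volume-conductor `uw_mesh` (2D or 3D; may also be
#'   M-only, in which case only the interstitial potential is computed)
#' @param v_m numeric vector of transmembrane potential: either one value
#'   per mesh node (non-M nodes ignored) or per node of the M submesh
#' @param conductivity a [conductivity_model()]
#' @param tensor_field extracellular tensor field on M (e.g. from
#'   [assemble_tensor_field()] with a fiber field); isotropic `sigma_et`
#'   if omitted
#' @param lambda vernix switch: 0 insulated fetal surface, nonzero
#'   conductive fetal compartment
#' @return a `potential_solution`: list with `phi` (nodal, NA on excluded
#'   fetal nodes), `gauge` (description), `rhs`, and the assembled operator
#'   kept for reuse via attribute `factor_env`
#' @export
solve_potentials <- function(mesh, v_m, conductivity, tensor_field = NULL,
                             lambda = 0) {
  pre <- prepare_potential_solver(mesh, conductivity, tensor_field, lambda)
  solve_potentials_prepared(pre, v_m)
}

# build operators once (factorisation reused across snapshots)
prepare_potential_solver <- function(mesh, conductivity, tensor_field = NULL,
                                     lambda = 0) {
  lab <- mesh$elem_label
  include <- lab != COMPARTMENT_CODES["F"] | lambda != 0
  sel <- which(include)
  if (length(sel) == 0L) stop("solve_potentials: no conductive elements")
  grads <- p1_gradients(mesh)
  G <- volume_conductor_tensors(mesh, conductivity, tensor_field, lambda)
  K <- assemble_stiffness(mesh, G, elements = sel, grads = grads)
  elM <- which(lab == COMPARTMENT_CODES["M"])
  if (is.null(tensor_field))
    tensor_field <- isotropic_tensor_field(conductivity$sigma_et)
  Ge <- element_tensors(mesh, tensor_field)
  Gi <- conductivity$varsigma * Ge
  Ki <- assemble_stiffness(mesh, Gi, elements = elM, grads = grads)
  active <- rep(FALSE, nrow(mesh$nodes))
  active[as.integer(mesh$elems[sel, ])] <- TRUE
  gauge_nodes <- if (!is.null(mesh$facets)) {
    da <- mesh$facet_label == BOUNDARY_CODES["dA"]
    unique(as.integer(mesh$facets[da, ]))
  } else integer(0)
  if (length(gauge_nodes) == 0L) gauge_nodes <- which(active)
  elM_nodes <- sort(unique(as.integer(mesh$elems[elM, ])))
  list(mesh = mesh, K = K, Ki = Ki, active = active,
       gauge_nodes = gauge_nodes, elM_nodes = elM_nodes, lambda = lambda)
}

solve_potentials_prepared <- function(pre, v_m) {
  mesh <- pre$mesh
  n <- nrow(mesh$nodes)
  vfull <- numeric(n)
  if (length(v_m) == n) {
    vfull <- as.numeric(v_m)
  } else if (length(v_m) == length(pre$elM_nodes)) {
    vfull[pre$elM_nodes] <- as.numeric(v_m)
  } else {
    stop("solve_potentials: v_m length (", length(v_m),
         ") matches neither the mesh (", n, ") nor its myometrial nodes (",
         length(pre$elM_nodes), ")")
  }
  b <- -as.numeric(pre$Ki %*% vfull)
  phi <- solve_neumann(pre$K, b, pre$active, pre$gauge_nodes)
  structure(list(phi = phi, rhs = b,
                 gauge = "zero mean over abdominal-surface nodes",
                 lambda = pre$lambda),
            class = "potential_solution")
}

#' Solve the potential problem for a time series of v_m snapshots
#'
#' Quasi-statics: each time instant is an independent elliptic solve; the
#' operator is assembled and factorised once.
#'
#' @param mesh full volume-conductor mesh
#' @param series [field_series()] of v_m on the myometrial submesh (values
#'   per M node) or on the full mesh
#' @param conductivity a [conductivity_model()]
#' @param tensor_field optional extracellular tensor field on M
#' @param lambda vernix switch
#' @param times subset of time stamps to solve (default: all)
#' @return [field_series()] of the potential (NA rows on excluded nodes)
#' @export
solve_potential_series <- function(mesh, series, conductivity,
                                   tensor_field = NULL, lambda = 0,
                                   times = NULL) {
  pre <- prepare_potential_solver(mesh, conductivity, tensor_field, lambda)
  if (is.null(times)) times <- series$times
  idx <- vapply(times, function(t) which.min(abs(series$times - t)), 1L)
  out <- matrix(NA_real_, nrow(mesh$nodes), length(idx))
  for (j in seq_along(idx)) {
    out[, j] <- solve_potentials_prepared(pre, series$values[, idx[j]])$phi
  }
  field_series(series$times[idx], out, mesh, "phi", "V")
}

#' Right-hand side of a point current dipole
#'
#' Load vector for a current dipole with moment `p` (A m) at `position`,
#' i.e. \eqn{b_i = p\cdot\nabla\lambda_i} on the vertices of the containing
#' element. Intended for validating the volume-conductor solver against
#' closed-form sphere solutions.
#'
#' @param mesh a `uw_mesh`
#' @param position length-3 (or dim) location inside the mesh
#' @param moment dipole moment vector (A m)
#' @return list with `b` (nodal load vector) and `element` (containing
#'   element index)
#' @export
dipole_source <- function(mesh, position, moment) {
  d <- mesh$dim
  position <- as.numeric(position)[seq_len(d)]
  moment <- as.numeric(moment)[seq_len(d)]
  grads <- p1_gradients(mesh)
  # locate the containing element via barycentric coordinates
  el <- mesh$elems
  ctr <- element_centroids(mesh)
  # candidates: elements whose circumscribing ball about the centroid
  # contains the point
  d2 <- rowSums(sweep(ctr, 2, position)^2)
  rmax2 <- 0
  for (j in seq_len(d + 1L))
    rmax2 <- pmax(rmax2, rowSums((mesh$nodes[el[, j], , drop = FALSE] - ctr)^2))
  cand <- which(d2 <= rmax2 * (1 + 1e-9))
  found <- NA_integer_; best <- -Inf
  for (e in cand) {
    verts <- mesh$nodes[el[e, ], , drop = FALSE]
    lam <- barycentric(verts, position)
    if (min(lam) > best) { best <- min(lam); found <- e }
    if (best > 1e-9) break
  }
  if (is.na(found) || best < -1e-6)
    stop("dipole_source: position not inside the mesh")
  b <- numeric(nrow(mesh$nodes))
  for (j in seq_len(d + 1L))
    b[el[found, j]] <- b[el[found, j]] + sum(moment * grads$grads[found, j, ])
  list(b = b, element = found)
}

barycentric <- function(verts, p) {
  d <- length(p)
  A <- t(verts[-1, , drop = FALSE]) - verts[1, ]
  lam_rest <- solve(A, p - verts[1, ])
  c(1 - sum(lam_rest), lam_rest)
}

#' Potential of a dipole in the meshed conductor
#'
#' Solves the pure-Neumann problem \eqn{\nabla\cdot(G\nabla\phi) =
#' \nabla\cdot(p\,\delta(r-r_0))} on the given mesh with per-compartment
#' conductivities, gauged to zero mean over the outer boundary nodes.
#' Validation helper for the concentric-spheres oracles.
#'
#' Two discretisations of the singular source are available: `"direct"`
#' loads the dipole on the P1 basis of the containing element;
#' `"subtraction"` (default for homogeneous conductors) splits
#' \eqn{\phi = \phi_\infty + \psi} with
#' \eqn{\phi_\infty = p\cdot(r-r_0)/(4\pi\sigma_0\|r-r_0\|^3)} the
#' free-space dipole potential and solves for the smooth correction
#' \eqn{\psi} with the boundary load \eqn{-\sigma\,n\cdot\nabla\phi_\infty},
#' which converges much faster near the singularity.
#'
#' @param mesh a `uw_mesh`
#' @param position dipole location (m)
#' @param moment dipole moment (A m)
#' @param conductivity a [conductivity_model()] (isotropic compartments;
#'   myometrium uses `sigma_et` isotropically unless a `tensor_field` is
#'   given)
#' @param tensor_field optional anisotropic tensor field for M
#' @param lambda vernix switch
#' @param method `"subtraction"` (homogeneous conductors only) or
#'   `"direct"`
#' @return a `potential_solution`
#' @export
solve_dipole_potential <- function(mesh, position, moment, conductivity,
                                   tensor_field = NULL, lambda = 0,
                                   method = c("subtraction", "direct")) {
  method <- match.arg(method)
  pre <- prepare_potential_solver(mesh, conductivity, tensor_field, lambda)
  if (method == "direct") {
    src <- dipole_source(mesh, position, moment)
    phi <- solve_neumann(pre$K, src$b, pre$active, pre$gauge_nodes)
    return(structure(list(phi = phi, rhs = src$b,
                          gauge = "zero mean over abdominal-surface nodes",
                          lambda = lambda, element = src$element),
                     class = "potential_solution"))
  }
  # subtraction method: requires a homogeneous conductor
  labs <- unique(mesh$elem_label)
  sig_of <- c(conductivity$G_F, conductivity$G_U, conductivity$sigma_et,
              conductivity$G_A)
  sigs <- sig_of[labs]
  if (lambda == 0) sigs <- sigs[labs != COMPARTMENT_CODES["F"]]
  if (length(unique(round(sigs, 12))) > 1L)
    stop("solve_dipole_potential: subtraction method requires a ",
         "homogeneous conductor; use method = 'direct'")
  sigma0 <- sigs[1]
  d <- mesh$dim
  position <- as.numeric(position)[seq_len(d)]
  moment <- as.numeric(moment)[seq_len(d)]
  phi_inf <- function(pts) {
    dx <- sweep(pts, 2, position)
    r3 <- rowSums(dx^2)^(1.5)
    (dx %*% moment) / (4 * pi * sigma0 * r3)
  }
  grad_phi_inf <- function(pts) {
    dx <- sweep(pts, 2, position)
    r2 <- rowSums(dx^2); r <- sqrt(r2)
    pr <- drop(dx %*% moment)
    (sweep(dx, 1, 3 * pr / r2, "*") - matrix(moment, nrow(pts), d, byrow = TRUE)) /
      (4 * pi * sigma0 * r2 * r) * (-1)
  }
  # boundary load b_i = - sum_facets int lambda_i sigma n . grad(phi_inf);
  # mid-edge quadrature (exact for quadratic integrands)
  b <- numeric(nrow(mesh$nodes))
  f <- mesh$facets
  if (is.null(f) || nrow(f) == 0L)
    stop("solve_dipole_potential: mesh has no boundary facets")
  # outer-facet normals: radial from the facet centroid (spherical surfaces)
  areas <- facet_areas(mesh)
  for (i in seq_len(nrow(f))) {
    vid <- f[i, ]
    verts <- mesh$nodes[vid, , drop = FALSE]
    ctr <- colMeans(verts)
    # normal of the facet plane, oriented outward (away from the domain
    # centroid at the origin-ish): use the centroid direction
    if (d == 3L) {
      nvec <- crossprod3(verts[2, ] - verts[1, ], verts[3, ] - verts[1, ])
      nvec <- nvec / sqrt(sum(nvec^2))
      if (sum(nvec * ctr) < 0) nvec <- -nvec
      qp <- rbind((verts[1, ] + verts[2, ]) / 2,
                  (verts[2, ] + verts[3, ]) / 2,
                  (verts[3, ] + verts[1, ]) / 2)
      w <- rep(areas[i] / 3, 3)
      lam <- rbind(c(0.5, 0.5, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5))
    } else {
      tvec <- verts[2, ] - verts[1, ]
      nvec <- c(tvec[2], -tvec[1]); nvec <- nvec / sqrt(sum(nvec^2))
      if (sum(nvec * ctr) < 0) nvec <- -nvec
      qp <- rbind(ctr)
      w <- areas[i]
      lam <- rbind(c(0.5, 0.5))
    }
    gn <- drop(grad_phi_inf(qp) %*% nvec)
    for (q in seq_along(w))
      b[vid] <- b[vid] - sigma0 * w[q] * gn[q] * lam[q, ]
  }
  psi <- solve_neumann(pre$K, b, pre$active, pre$gauge_nodes)
  phi <- psi + drop(phi_inf(mesh$nodes))
  phi <- phi - mean(phi[pre$gauge_nodes])
  structure(list(phi = phi, rhs = b,
                 gauge = "zero mean over abdominal-surface nodes",
                 lambda = lambda, sigma0 = sigma0),
            class = "potential_solution")
}

crossprod3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                               a[3] * b[1] - a[1] * b[3],
                               a[1] * b[2] - a[2] * b[1])

#' Potentials driven by a distributed primary current density
#'
#' Solves \eqn{\nabla\cdot(G\nabla\phi) = \nabla\cdot J_p} for a smooth,
#' user-supplied primary (impressed) current density, with the same
#' boundary conditions and gauge as [solve_potentials()]. The load vector is
#' \eqn{b_i = \int J_p\cdot\nabla\lambda_i} by element-midpoint quadrature.
#' Useful for validating the quasi-static machinery against closed-form
#' spherical-conductor solutions with compact current blobs.
#'
#' @param mesh a `uw_mesh`
#' @param J_p function mapping an n x dim matrix of positions to an n x dim
#'   matrix of primary current densities (A/m^2)
#' @param conductivity a [conductivity_model()]
#' @param tensor_field optional anisotropic tensor field for M
#' @param lambda vernix switch
#' @return a `potential_solution`
#' @export
solve_primary_potential <- function(mesh, J_p, conductivity,
                                    tensor_field = NULL, lambda = 0) {
  pre <- prepare_potential_solver(mesh, conductivity, tensor_field, lambda)
  grads <- p1_gradients(mesh)
  ctr <- element_centroids(mesh)
  Jv <- J_p(ctr)
  d <- mesh$dim
  b <- numeric(nrow(mesh$nodes))
  el <- mesh$elems
  for (j in seq_len(d + 1L)) {
    contrib <- numeric(nrow(el))
    for (a in seq_len(d)) contrib <- contrib + Jv[, a] * grads$grads[, j, a]
    contrib <- contrib * grads$vol
    acc <- tapply(contrib, el[, j], sum)
    b[as.integer(names(acc))] <- b[as.integer(names(acc))] + as.numeric(acc)
  }
  phi <- solve_neumann(pre$K, b, pre$active, pre$gauge_nodes)
  structure(list(phi = phi, rhs = b,
                 gauge = "zero mean over abdominal-surface nodes",
                 lambda = lambda),
            class = "potential_solution")
}
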