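# ---------------------------------------------------------------------------
# Structured simplicial meshes for spheres, shells, annuli and cables.
# All generators are deterministic; no external mesher is used so that test
# fixtures are bit-stable across platforms.
# ---------------------------------------------------------------------------

new_mesh <- function(nodes, elems, elem_label, facets, facet_label, dim,
                     resolution = NA_real_) {
  m <- structure(list(
    nodes = nodes, elems = elems, elem_label = as.integer(elem_label),
    facets = facets, facet_label = as.integer(facet_label),
    dim = as.integer(dim), resolution = resolution), class = "uw_mesh")
  validate_mesh(m)
  m
}

validate_mesh <- function(m) {
  if (nrow(m$elems) != length(m$elem_label))
    stop("mesh: one compartment label per element required")
  if (!is.null(m$facets) && nrow(m$facets) != length(m$facet_label))
    stop("mesh: one boundary label per facet required")
  used <- sort(unique(as.integer(m$elems)))
  if (min(used) < 1L || max(used) > nrow(m$nodes))
    stop("mesh: element connectivity out of node range")
  if (length(setdiff(seq_len(nrow(m$nodes)), used)) > 0L)
    stop("mesh: orphan nodes present")
  v <- element_volumes(m)
  if (any(v <= 0)) stop("mesh: non-positive element volume (",
                        sum(v <= 0), " elements)")
  invisible(m)
}

#' @export
print.uw_mesh <- function(x, ...) {
  cat(sprintf("uw_mesh: dim %d, %d nodes, %d elements, %d tagged facets\n",
              x$dim, nrow(x$nodes), nrow(x$elems),
              if (is.null(x$facets)) 0L else nrow(x$facets)))
  tab <- table(compartment_name(x$elem_label))
  cat("  compartments:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Element measures (length, area or volume)
#'
#' @param mesh a `uw_mesh`
#' @return numeric vector of element measures (m^dim)
#' @export
element_volumes <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elems; d <- mesh$dim
  if (d == 1L) {
    abs(nd[el[, 2], 1] - nd[el[, 1], 1])
  } else if (d == 2L) {
    x1 <- nd[el[, 1], , drop = FALSE]; x2 <- nd[el[, 2], , drop = FALSE]
    x3 <- nd[el[, 3], , drop = FALSE]
    abs((x2[, 1] - x1[, 1]) * (x3[, 2] - x1[, 2]) -
        (x3[, 1] - x1[, 1]) * (x2[, 2] - x1[, 2])) / 2
  } else {
    a <- nd[el[, 2], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
    b <- nd[el[, 3], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
    c <- nd[el[, 4], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
    abs(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
        a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
        a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
  }
}

#' Element centroids
#' @param mesh a `uw_mesh`
#' @return matrix (n_elem x dim)
#' @export
element_centroids <- function(mesh) {
  d1 <- ncol(mesh$elems)
  out <- 0
  for (j in seq_len(d1)) out <- out + mesh$nodes[mesh$elems[, j], , drop = FALSE]
  out / d1
}

#' Facet measures (point count 1, length or area)
#' @param mesh a `uw_mesh`
#' @return numeric vector, one entry per tagged facet
#' @export
facet_areas <- function(mesh) {
  f <- mesh$facets; nd <- mesh$nodes
  if (is.null(f) || nrow(f) == 0L) return(numeric(0))
  if (mesh$dim == 1L) return(rep(1, nrow(f)))
  if (mesh$dim == 2L) {
    dx <- nd[f[, 2], , drop = FALSE] - nd[f[, 1], , drop = FALSE]
    return(sqrt(rowSums(dx^2)))
  }
  a <- nd[f[, 2], , drop = FALSE] - nd[f[, 1], , drop = FALSE]
  b <- nd[f[, 3], , drop = FALSE] - nd[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sqrt(rowSums(cr^2)) / 2
}

#' Total measure of a compartment
#' @param mesh a `uw_mesh`
#' @param compartment name ("F","U","M","A") or integer code
#' @export
compartment_volume <- function(mesh, compartment) {
  code <- if (is.character(compartment)) compartment_code(compartment) else compartment
  sum(element_volumes(mesh)[mesh$elem_label == code])
}

# --- unit icosphere -------------------------------------------------------

# subdivided icosahedron projected to the unit sphere; deterministic ordering
icosphere <- function(nsub) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  if (nsub > 1L) {
    # barycentric lattice refinement of each face, vertices deduplicated
    key_env <- new.env(hash = TRUE, parent = emptyenv())
    verts <- list(); nv <- 0L
    get_vertex <- function(p) {
      p <- p / sqrt(sum(p^2))
      key <- paste(sprintf("%.12f", round(p, 12)), collapse = ",")
      id <- key_env[[key]]
      if (is.null(id)) {
        nv <<- nv + 1L; verts[[nv]] <<- p; key_env[[key]] <- nv; id <- nv
      }
      id
    }
    faces <- vector("list", nrow(f) * nsub^2); nf <- 0L
    for (fi in seq_len(nrow(f))) {
      A <- v[f[fi, 1], ]; B <- v[f[fi, 2], ]; C <- v[f[fi, 3], ]
      # lattice point (i, j): A + i/n (B-A) + j/n (C-A), j <= n - i
      idx <- matrix(0L, nsub + 1L, nsub + 1L)
      for (i in 0:nsub) for (j in 0:(nsub - i)) {
        p <- A + (i / nsub) * (B - A) + (j / nsub) * (C - A)
        idx[i + 1L, j + 1L] <- get_vertex(p)
      }
      for (i in 0:(nsub - 1L)) for (j in 0:(nsub - 1L - i)) {
        nf <- nf + 1L
        faces[[nf]] <- c(idx[i + 1L, j + 1L], idx[i + 2L, j + 1L], idx[i + 1L, j + 2L])
        if (j < nsub - 1L - i) {
          nf <- nf + 1L
          faces[[nf]] <- c(idx[i + 2L, j + 1L], idx[i + 2L, j + 2L], idx[i + 1L, j + 2L])
        }
      }
    }
    v <- do.call(rbind, verts)
    f <- do.call(rbind, faces[seq_len(nf)])
  }
  # outward orientation
  n1 <- v[f[, 2], ] - v[f[, 1], ]
  n2 <- v[f[, 3], ] - v[f[, 1], ]
  cr <- cbind(n1[, 2] * n2[, 3] - n1[, 3] * n2[, 2],
              n1[, 3] * n2[, 1] - n1[, 1] * n2[, 3],
              n1[, 1] * n2[, 2] - n1[, 2] * n2[, 1])
  ctr <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  flip <- rowSums(cr * ctr) < 0
  f[flip, c(2, 3)] <- f[flip, c(3, 2)]
  list(vertices = v, faces = f)
}

# split the prism between two radial copies of a surface triangle into 3 tets
# using the vertex-index ordering rule (conforming across shared quad faces)
prism_tets <- function(face, off_bot, off_top) {
  o <- order(face)
  a <- off_bot + face[o]; b <- off_top + face[o]
  rbind(c(a[1], a[2], a[3], b[1]),
        c(a[2], a[3], b[1], b[2]),
        c(a[3], b[1], b[2], b[3]))
}

# radial layer specification for a set of compartments
# returns data.frame(radius_lo, radius_hi fractions f in [0,1] of band, ...)
radial_bands <- function(geometry, resolution, compartments,
                         min_wall_layers = 2L) {
  cfg <- geometry$config
  rads <- c(0, cfg$r_fetus, cfg$r_myo_outer - cfg$wall_thickness,
            cfg$r_myo_outer)
  names(rads) <- c("origin", "dF", "dU", "dM")
  bands <- list(
    F = c(0, rads["dF"]),
    U = c(rads["dF"], rads["dU"]),
    M = c(rads["dU"], rads["dM"]),
    A = c(rads["dM"], NA))  # outer radius is direction dependent
  out <- list()
  for (comp in c("F", "U", "M", "A")) {
    if (!(comp %in% compartments)) next
    b <- bands[[comp]]
    thick <- if (comp == "A") cfg$r_abdomen - sqrt(sum(cfg$abdomen_offset^2)) - b[1]
             else b[2] - b[1]
    if (thick / resolution < 0.2)
      stop("generate_mesh: resolution ", resolution,
           " too coarse to resolve compartment ", comp,
           " (fewer than one element across thickness ",
           signif(thick, 4), " m)")
    n <- max(1L, as.integer(round(thick / resolution)))
    if (comp == "M") n <- max(n, min_wall_layers)
    out[[comp]] <- list(comp = comp, lo = b[1], hi = b[2], n = n)
  }
  out
}

# ---------------------------------------------------------------------------

#' Uniform 1D cable mesh
#'
#' A uniform segment mesh of given length, labelled as myometrium, with the
#' two end nodes tagged as the inner (`dU`) and outer (`dM`) boundaries.
#'
#' @param length cable length (m)
#' @param resolution target segment length (m)
#' @return a `uw_mesh` of dimension 1
#' @export
mesh_cable <- function(length = 0.2, resolution = 1e-3) {
  if (resolution <= 0) stop("mesh_cable: resolution must be > 0")
  n <- max(2L, as.integer(round(length / resolution)) + 1L)
  x <- matrix(seq(0, length, length.out = n), ncol = 1)
  el <- cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
  new_mesh(x, el, rep(COMPARTMENT_CODES["M"], n - 1L),
           facets = matrix(c(1L, n), ncol = 1),
           facet_label = c(BOUNDARY_CODES["dU"], BOUNDARY_CODES["dM"]),
           dim = 1L, resolution = resolution)
}

# --- 2D: polar structured disk / annulus ----------------------------------

mesh_polar <- function(geometry, resolution, compartments) {
  cfg <- geometry$config
  bands <- radial_bands(geometry, resolution, compartments)
  if (length(bands) == 0L) stop("generate_mesh: no compartments selected")
  r_ref <- max(vapply(bands, function(b)
    if (is.na(b$hi)) cfg$r_abdomen else b$hi, 1))
  nt <- max(12L, as.integer(round(2 * pi * r_ref / resolution)))
  theta <- seq(0, 2 * pi, length.out = nt + 1L)[-(nt + 1L)]
  u <- cbind(cos(theta), sin(theta))
  # outer radius along each direction for the abdomen band (2D section z = 0)
  ca <- cfg$abdomen_offset[1:2]; ra <- cfg$r_abdomen
  r_outer <- drop(u %*% ca) + sqrt(drop(u %*% ca)^2 + ra^2 - sum(ca^2))

  has_core <- !is.null(bands$F)
  nodes <- if (has_core) matrix(0, 1, 2) else matrix(0, 0, 2)
  ring_off <- integer(0)   # node offset of each ring
  ring_r <- list()         # per-ring radius vector (length nt)
  add_ring <- function(rv) {
    ring_off <<- c(ring_off, nrow(nodes))
    nodes <<- rbind(nodes, u * rv)
    ring_r[[length(ring_r) + 1L]] <<- rv
  }
  elems <- list(); labs <- integer(0)
  facets <- list(); flabs <- integer(0)
  iface_of <- c(F = "dF", U = "dU", M = "dM", A = "dA")

  first <- TRUE
  for (b in bands) {
    lo <- b$lo; hi <- b$hi
    lo_v <- rep(lo, nt)
    hi_v <- if (b$comp == "A") r_outer else rep(hi, nt)
    for (l in seq_len(b$n)) {
      fr <- l / b$n
      rv <- lo_v + fr * (hi_v - lo_v)
      if (first && lo == 0 && l == 1L && has_core) {
        add_ring(rv)
        # center fan
        o <- ring_off[length(ring_off)]
        for (i in seq_len(nt)) {
          j <- if (i == nt) 1L else i + 1L
          elems[[length(elems) + 1L]] <- c(1L, o + i, o + j)
          labs <- c(labs, compartment_code(b$comp))
        }
      } else {
        if (l == 1L && length(ring_off) == 0L) add_ring(lo_v)
        add_ring(rv)
        nr <- length(ring_off)
        o0 <- ring_off[nr - 1L]; o1 <- ring_off[nr]
        for (i in seq_len(nt)) {
          j <- if (i == nt) 1L else i + 1L
          elems[[length(elems) + 1L]] <- c(o0 + i, o0 + j, o1 + i)
          elems[[length(elems) + 1L]] <- c(o0 + j, o1 + j, o1 + i)
          labs <- c(labs, rep(compartment_code(b$comp), 2L))
        }
      }
      first <- FALSE
    }
    # interface facets at the outer surface of this band
    o <- ring_off[length(ring_off)]
    for (i in seq_len(nt)) {
      j <- if (i == nt) 1L else i + 1L
      facets[[length(facets) + 1L]] <- c(o + i, o + j)
      flabs <- c(flabs, boundary_code(iface_of[[b$comp]]))
    }
    # inner facet of the innermost band when it is not the origin
    if (b$comp == names(bands)[1] && lo > 0) {
      inner_name <- c(U = "dF", M = "dU", A = "dM")[[b$comp]]
      oi <- ring_off[length(ring_off) - b$n]
      for (i in seq_len(nt)) {
        j <- if (i == nt) 1L else i + 1L
        facets[[length(facets) + 1L]] <- c(oi + i, oi + j)
        flabs <- c(flabs, boundary_code(inner_name))
      }
    }
  }
  el <- do.call(rbind, elems)
  # fix orientation (positive area)
  x1 <- nodes[el[, 1], , drop = FALSE]; x2 <- nodes[el[, 2], , drop = FALSE]
  x3 <- nodes[el[, 3], , drop = FALSE]
  s <- (x2[, 1] - x1[, 1]) * (x3[, 2] - x1[, 2]) -
       (x3[, 1] - x1[, 1]) * (x2[, 2] - x1[, 2])
  el[s < 0, c(2, 3)] <- el[s < 0, c(3, 2)]
  new_mesh(nodes, el, labs, do.call(rbind, facets), flabs, 2L, resolution)
}

# --- 3D: layered icosphere ball / shell -----------------------------------

mesh_layered_sphere <- function(geometry, resolution, compartments,
                                min_wall_layers = 2L) {
  cfg <- geometry$config
  bands <- radial_bands(geometry, resolution, compartments, min_wall_layers)
  if (length(bands) == 0L) stop("generate_mesh: no compartments selected")
  r_ref <- max(vapply(bands, function(b)
    if (is.na(b$hi)) cfg$r_abdomen else b$hi, 1))
  nsub <- max(2L, as.integer(ceiling(1.06 * r_ref / resolution)))
  sph <- icosphere(nsub)
  V <- sph$vertices; Fc <- sph$faces
  nv <- nrow(V)
  r_outer <- geometry$outer_radius(V)  # direction-dependent abdomen radius

  has_core <- !is.null(bands$F)
  nodes <- if (has_core) matrix(0, 1, 3) else matrix(0, 0, 3)
  layer_off <- integer(0)
  add_layer <- function(rv) {
    layer_off <<- c(layer_off, nrow(nodes))
    nodes <<- rbind(nodes, V * rv)
  }
  elems <- list(); labs <- list()
  facets <- list(); flabs <- list()
  iface_of <- c(F = "dF", U = "dU", M = "dM", A = "dA")

  for (b in bands) {
    lo_v <- rep(b$lo, nv)
    hi_v <- if (b$comp == "A") r_outer else rep(b$hi, nv)
    for (l in seq_len(b$n)) {
      fr <- l / b$n
      rv <- lo_v + fr * (hi_v - lo_v)
      if (b$lo == 0 && l == 1L && has_core && length(layer_off) == 0L) {
        add_layer(rv)
        o <- layer_off[1L]
        core <- cbind(1L, o + Fc[, 1], o + Fc[, 2], o + Fc[, 3])
        elems[[length(elems) + 1L]] <- core
        labs[[length(labs) + 1L]] <- rep(compartment_code(b$comp), nrow(core))
      } else {
        if (length(layer_off) == 0L) add_layer(lo_v)
        add_layer(rv)
        nl <- length(layer_off)
        o0 <- layer_off[nl - 1L]; o1 <- layer_off[nl]
        tl <- vector("list", nrow(Fc))
        for (fi in seq_len(nrow(Fc))) tl[[fi]] <- prism_tets(Fc[fi, ], o0, o1)
        tt <- do.call(rbind, tl)
        elems[[length(elems) + 1L]] <- tt
        labs[[length(labs) + 1L]] <- rep(compartment_code(b$comp), nrow(tt))
      }
    }
    o <- layer_off[length(layer_off)]
    facets[[length(facets) + 1L]] <- o + Fc
    flabs[[length(flabs) + 1L]] <- rep(boundary_code(iface_of[[b$comp]]), nrow(Fc))
    if (b$comp == names(bands)[1] && b$lo > 0) {
      inner_name <- c(U = "dF", M = "dU", A = "dM")[[b$comp]]
      oi <- layer_off[length(layer_off) - b$n]
      facets[[length(facets) + 1L]] <- oi + Fc
      flabs[[length(flabs) + 1L]] <- rep(boundary_code(inner_name), nrow(Fc))
    }
  }
  el <- do.call(rbind, elems)
  # orient tets to positive volume
  a <- nodes[el[, 2], ] - nodes[el[, 1], ]
  b3 <- nodes[el[, 3], ] - nodes[el[, 1], ]
  c3 <- nodes[el[, 4], ] - nodes[el[, 1], ]
  s <- a[, 1] * (b3[, 2] * c3[, 3] - b3[, 3] * c3[, 2]) -
       a[, 2] * (b3[, 1] * c3[, 3] - b3[, 3] * c3[, 1]) +
       a[, 3] * (b3[, 1] * c3[, 2] - b3[, 2] * c3[, 1])
  el[s < 0, c(3, 4)] <- el[s < 0, c(4, 3)]
  new_mesh(nodes, el, unlist(labs), do.call(rbind, facets), unlist(flabs),
           3L, resolution)
}

#' Generate a conforming simplicial mesh of the volume-conductor geometry
#'
#' Structured, deterministic mesh generation: a uniform cable in 1D, a polar
#' disk/annulus grid in 2D (the z = 0 section of the geometry), and radially
#' layered subdivided-icosahedron tetrahedral meshes in 3D. Compartment
#' interfaces coincide with mesh layers, so every element lies in exactly one
#' compartment, and interface facets are tagged exactly. The uterine wall
#' receives at least `min_wall_layers` element layers.
#'
#' @param geometry a `uw_geometry` from [build_spherical_geometry()] (ignored
#'   for `dimension = 1`)
#' @param resolution target edge length (m)
#' @param dimension 1, 2 or 3
#' @param compartments subset of `c("F","U","M","A")` to mesh (contiguous
#'   bands); e.g. `"M"` gives the myometrial shell only
#' @param cable_length cable length for `dimension = 1` (m)
#' @param min_wall_layers minimum element layers across the uterine wall
#' @param seed unused (the generator is fully deterministic); accepted so
#'   that callers can record it in run manifests
#' @return a `uw_mesh`
#' @export
#' @examples
#' g <- build_spherical_geometry(geometry_config())
#' shell <- generate_mesh(g, resolution = 0.04, dimension = 3,
#'                        compartments = "M")
#' table(compartment_name(shell$elem_label))
generate_mesh <- function(geometry = NULL, resolution, dimension = 3L,
                          compartments = c("F", "U", "M", "A"),
                          cable_length = 0.2, min_wall_layers = 2L,
                          seed = NULL) {
  if (resolution <= 0) stop("generate_mesh: resolution must be > 0")
  dimension <- as.integer(dimension)
  if (dimension == 1L) return(mesh_cable(cable_length, resolution))
  if (is.null(geometry)) stop("generate_mesh: geometry required for dimension > 1")
  compartments <- match.arg(compartments, c("F", "U", "M", "A"),
                            several.ok = TRUE)
  # selected compartments must be contiguous bands
  allc <- c("F", "U", "M", "A")
  sel <- allc %in% compartments
  if (any(diff(which(sel)) > 1L))
    stop("generate_mesh: selected compartments must be contiguous")
  if (dimension == 2L) return(mesh_polar(geometry, resolution, compartments))
  if (dimension != 3L) stop("generate_mesh: dimension must be 1, 2 or 3")
  mesh_layered_sphere(geometry, resolution, compartments, min_wall_layers)
}

#' Re-derive boundary facet tags from the geometry
#'
#' Assigns each tagged facet to the nearest spherical interface (`dF`, `dU`,
#' `dM` about the origin, `dA` about the shifted abdominal centre) by its
#' vertex radii. A facet whose vertices do not match any interface within
#' tolerance, or that matches two interfaces, raises a tagging error naming
#' the facet.
#'
#' @param mesh a `uw_mesh` of dimension 2 or 3
#' @param geometry the `uw_geometry` the mesh conforms to
#' @param tol matching tolerance (m); default half the mesh resolution
#' @return the mesh with refreshed `facet_label`
#' @export
tag_boundaries <- function(mesh, geometry, tol = NULL) {
  if (is.null(mesh$facets) || nrow(mesh$facets) == 0L) return(mesh)
  if (mesh$dim == 1L) return(mesh)
  cfg <- geometry$config
  ifr <- c(dF = cfg$r_fetus, dU = cfg$r_myo_outer - cfg$wall_thickness,
           dM = cfg$r_myo_outer)
  if (is.null(tol)) {
    gap <- min(diff(sort(unname(ifr))))
    tol <- max(min(mesh$resolution / 2, 0.4 * gap, na.rm = TRUE), 1e-9)
  }
  nd2 <- if (ncol(mesh$nodes) == 2L) cbind(mesh$nodes, 0) else mesh$nodes
  lab <- integer(nrow(mesh$facets))
  for (i in seq_len(nrow(mesh$facets))) {
    vids <- mesh$facets[i, ]
    p <- nd2[vids, , drop = FALSE]
    r0 <- sqrt(rowSums(p^2))
    rA <- sqrt(rowSums(sweep(p, 2, cfg$abdomen_offset)^2))
    hits <- character(0)
    for (nm in names(ifr)) if (all(abs(r0 - ifr[[nm]]) < tol)) hits <- c(hits, nm)
    if (all(abs(rA - cfg$r_abdomen) < tol)) hits <- c(hits, "dA")
    if (length(hits) == 0L)
      stop("tag_boundaries: facet ", i, " matches no interface (vertex radii ",
           paste(signif(r0, 5), collapse = ", "), ")")
    if (length(hits) > 1L)
      stop("tag_boundaries: facet ", i, " is ambiguous between interfaces ",
           paste(hits, collapse = " and "))
    lab[i] <- boundary_code(hits)
  }
  mesh$facet_label <- lab
  mesh
}
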