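# ---------------------------------------------------------------------------
# First-order (P1) simplicial finite elements in 1, 2 and 3 dimensions:
# barycentric basis gradients, lumped/consistent mass, anisotropic stiffness.
# Assembly is vectorised over elements; sparse matrices via Matrix.
# ---------------------------------------------------------------------------

# per-element P1 basis gradients and measures
# returns list(grads = array (nelem, d+1, d), vol = numeric(nelem))
p1_gradients <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elems; d <- mesh$dim
  ne <- nrow(el)
  vol <- element_volumes(mesh)
  g <- array(0, c(ne, d + 1L, d))
  if (d == 1L) {
    L <- nd[el[, 2], 1] - nd[el[, 1], 1]
    g[, 1, 1] <- -1 / L
    g[, 2, 1] <- 1 / L
  } else if (d == 2L) {
    e2 <- nd[el[, 2], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
    e3 <- nd[el[, 3], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
    det <- e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1]
    g[, 2, 1] <- e3[, 2] / det; g[, 2, 2] <- -e3[, 1] / det
    g[, 3, 1] <- -e2[, 2] / det; g[, 3, 2] <- e2[, 1] / det
    g[, 1, ] <- -(g[, 2, ] + g[, 3, ])
  } else {
    e2 <- nd[el[, 2], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
    e3 <- nd[el[, 3], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
    e4 <- nd[el[, 4], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
    cx <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                               a[, 3] * b[, 1] - a[, 1] * b[, 3],
                               a[, 1] * b[, 2] - a[, 2] * b[, 1])
    c34 <- cx(e3, e4); c42 <- cx(e4, e2); c23 <- cx(e2, e3)
    det <- rowSums(e2 * c34)
    g[, 2, ] <- c34 / det
    g[, 3, ] <- c42 / det
    g[, 4, ] <- c23 / det
    g[, 1, ] <- -(g[, 2, ] + g[, 3, ] + g[, 4, ])
  }
  list(grads = g, vol = vol)
}

# evaluate a tensor specification on elements -> array (d, d, nelem)
# spec may be: a tensor_field function (evaluated at centroids, truncated to
# the mesh dimension), a scalar, a numeric vector (one isotropic value per
# element), or an array (d, d, nelem)
element_tensors <- function(mesh, spec) {
  d <- mesh$dim; ne <- nrow(mesh$elems)
  if (inherits(spec, "tensor_field") || is.function(spec)) {
    ctr <- element_centroids(mesh)
    G3 <- spec(as_points3(ctr))
    return(G3[seq_len(d), seq_len(d), , drop = FALSE])
  }
  if (is.array(spec) && length(dim(spec)) == 3L) return(spec)
  val <- if (length(spec) == 1L) rep(as.numeric(spec), ne) else as.numeric(spec)
  out <- array(0, c(d, d, ne))
  for (k in seq_len(d)) out[k, k, ] <- val
  out
}

# stiffness matrix K[i, j] = int grad phi_i . G grad phi_j over the listed
# elements (all by default); symmetric positive semidefinite, null space =
# constants (pure Neumann)
assemble_stiffness <- function(mesh, tensors, elements = NULL,
                               grads = NULL) {
  d <- mesh$dim; nvert <- d + 1L
  if (is.null(grads)) grads <- p1_gradients(mesh)
  el <- mesh$elems
  sel <- if (is.null(elements)) seq_len(nrow(el)) else elements
  G <- element_tensors(mesh, tensors)
  if (dim(G)[3] == nrow(el) && length(sel) != nrow(el))
    G <- G[, , sel, drop = FALSE]
  g <- grads$grads[sel, , , drop = FALSE]
  vol <- grads$vol[sel]
  ne <- length(sel)
  # Gg[[j]][, a] = (G grad_j)_a per element
  Gg <- vector("list", nvert)
  for (j in seq_len(nvert)) {
    m <- matrix(0, ne, d)
    for (a in seq_len(d)) for (b in seq_len(d))
      m[, a] <- m[, a] + G[a, b, ] * g[, j, b]
    Gg[[j]] <- m
  }
  nn <- nvert * nvert * ne
  ii <- integer(nn); jj <- integer(nn); xx <- numeric(nn)
  pos <- 0L
  for (i in seq_len(nvert)) for (j in seq_len(nvert)) {
    idx <- pos + seq_len(ne)
    ii[idx] <- el[sel, i]
    jj[idx] <- el[sel, j]
    kij <- numeric(ne)
    for (a in seq_len(d)) kij <- kij + g[, i, a] * Gg[[j]][, a]
    xx[idx] <- kij * vol
    pos <- pos + ne
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(mesh$nodes), nrow(mesh$nodes)))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

# lumped mass vector (row sums of the consistent mass matrix)
lumped_mass <- function(mesh, elements = NULL) {
  el <- mesh$elems
  sel <- if (is.null(elements)) seq_len(nrow(el)) else elements
  vol <- element_volumes(mesh)[sel]
  nvert <- ncol(el)
  m <- numeric(nrow(mesh$nodes))
  for (j in seq_len(nvert)) {
    acc <- tapply(vol / nvert, el[sel, j], sum)
    m[as.integer(names(acc))] <- m[as.integer(names(acc))] + as.numeric(acc)
  }
  m
}

# consistent mass matrix M[i, j] = int phi_i phi_j
consistent_mass <- function(mesh, elements = NULL) {
  el <- mesh$elems; d <- mesh$dim; nvert <- d + 1L
  sel <- if (is.null(elements)) seq_len(nrow(el)) else elements
  vol <- element_volumes(mesh)[sel]
  ne <- length(sel)
  nn <- nvert * nvert * ne
  ii <- integer(nn); jj <- integer(nn); xx <- numeric(nn)
  base <- 1 / ((d + 1) * (d + 2))
  pos <- 0L
  for (i in seq_len(nvert)) for (j in seq_len(nvert)) {
    idx <- pos + seq_len(ne)
    ii[idx] <- el[sel, i]; jj[idx] <- el[sel, j]
    xx[idx] <- vol * base * (1 + (i == j))
    pos <- pos + ne
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(mesh$nodes), nrow(mesh$nodes)))
  Matrix::forceSymmetric((M + Matrix::t(M)) / 2)
}

# per-element gradient of a nodal field: matrix (nelem, d)
field_gradient <- function(mesh, v, grads = NULL) {
  if (is.null(grads)) grads <- p1_gradients(mesh)
  d <- mesh$dim; el <- mesh$elems
  out <- matrix(0, nrow(el), d)
  for (j in seq_len(ncol(el)))
    for (a in seq_len(d))
      out[, a] <- out[, a] + v[el[, j]] * grads$grads[, j, a]
  out
}

# extract the submesh of one compartment, keeping the node correspondence
# returns list(mesh, node_map) with node_map[i] = index in the parent mesh
submesh <- function(mesh, compartment) {
  code <- if (is.character(compartment)) compartment_code(compartment) else compartment
  keep <- mesh$elem_label == code
  el <- mesh$elems[keep, , drop = FALSE]
  used <- sort(unique(as.integer(el)))
  remap <- integer(nrow(mesh$nodes)); remap[used] <- seq_along(used)
  el2 <- matrix(remap[el], nrow = nrow(el))
  fl <- NULL; flab <- integer(0)
  if (!is.null(mesh$facets)) {
    fk <- apply(matrix(mesh$facets %in% used, nrow = nrow(mesh$facets)), 1, all)
    if (any(fk)) {
      fl <- matrix(remap[mesh$facets[fk, , drop = FALSE]], nrow = sum(fk))
      flab <- mesh$facet_label[fk]
    }
  }
  m <- new_mesh(mesh$nodes[used, , drop = FALSE], el2,
                mesh$elem_label[keep], fl, flab, mesh$dim, mesh$resolution)
  list(mesh = m, node_map = used)
}
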