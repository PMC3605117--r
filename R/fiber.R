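# ---------------------------------------------------------------------------
# Myometrial fiber-direction design.
#
# The uterine wall is viewed as a union of closed layers f(r) = const. At
# each point a local orthonormal frame {n, t1, t2} is erected from the layer
# normal and the curve of symmetry C (the fundus-to-cervix axis); the fiber
# direction is a3 = t1 cos(alpha) + t2 sin(alpha). Points where the curve
# tangent is parallel to the layer normal (the poles) have no well-defined
# frame and are mapped to a3 = 0, i.e. isotropic conductivity.
# ---------------------------------------------------------------------------

#' Fiber-field specification
#'
#' @param f implicit layer function `f(r)` (vectorised over an n x 3 matrix);
#'   layers are its level sets
#' @param curve parametric curve of symmetry `r_C(t)` returning a length-3
#'   point; parameterised from the fundus towards the cervix
#' @param t_range parameter range `c(t1, t2)` of the curve
#' @param alpha fiber orientation angle (rad) with respect to the meridional
#'   tangent `t1`; a constant or a function of position
#' @param grad_f optional analytic gradient `grad_f(r)` (n x 3); a central
#'   finite difference is used otherwise
#' @return a `fiber_spec` object
#' @export
fiber_spec <- function(f, curve, t_range, alpha = 0, grad_f = NULL) {
  if (!is.function(f) || !is.function(curve))
    stop("fiber_spec: f and curve must be functions")
  if (!is.numeric(t_range) || length(t_range) != 2L || t_range[1] >= t_range[2])
    stop("fiber_spec: t_range must be an increasing pair")
  alpha_fun <- if (is.function(alpha)) alpha else function(r) rep(alpha, nrow(as_points3(r)))
  structure(list(f = f, curve = curve, t_range = t_range,
                 alpha = alpha_fun, grad_f = grad_f),
            class = "fiber_spec")
}

#' Spherical-uterus fiber specification
#'
#' Layers are spheres about the origin; the curve of symmetry is the z axis
#' traversed from the fundus (+z) to the cervix (-z).
#'
#' @param R nominal layer radius (m); only used for the parameter range
#' @param alpha orientation angle (rad), constant or function of position
#' @return a [fiber_spec()]
#' @export
spherical_fiber_spec <- function(R = 0.155, alpha = 0) {
  fiber_spec(
    f = function(r) sqrt(rowSums(as_points3(r)^2)) - R,
    curve = function(t) c(0, 0, -t),     # fundus (+z) at t = -R
    t_range = c(-2 * R, 2 * R),
    alpha = alpha,
    grad_f = function(r) {
      r <- as_points3(r)
      r / sqrt(rowSums(r^2))
    })
}

grad_numeric <- function(f, r, h = 1e-7) {
  r <- as_points3(r)
  g <- matrix(0, nrow(r), 3)
  for (j in 1:3) {
    e <- matrix(0, nrow(r), 3); e[, j] <- h
    g[, j] <- (f(r + e) - f(r - e)) / (2 * h)
  }
  g
}

# nearest perpendicular foot on the curve: t0 with <c'(t0), c(t0) - r> = 0,
# found by dense sampling plus local root refinement
nearest_foot <- function(spec, r, n_samples = 400L, tol = 1e-10) {
  tt <- seq(spec$t_range[1], spec$t_range[2], length.out = n_samples)
  h <- diff(spec$t_range) / (n_samples - 1L)
  cv <- t(vapply(tt, spec$curve, numeric(3)))
  dv <- (t(vapply(pmin(tt + h / 2, spec$t_range[2]), spec$curve, numeric(3))) -
         t(vapply(pmax(tt - h / 2, spec$t_range[1]), spec$curve, numeric(3)))) / h
  gfun <- function(t) {
    c0 <- spec$curve(t)
    d0 <- (spec$curve(min(t + 1e-6, spec$t_range[2])) -
           spec$curve(max(t - 1e-6, spec$t_range[1]))) /
      (min(t + 1e-6, spec$t_range[2]) - max(t - 1e-6, spec$t_range[1]))
    sum(d0 * (c0 - r))
  }
  g <- rowSums(dv * sweep(cv, 2, r))
  dist2 <- rowSums(sweep(cv, 2, r)^2)
  # sign changes of g, keep the closest root
  sc <- which(g[-length(g)] * g[-1] <= 0)
  best_t <- NA_real_; best_d <- Inf
  for (i in sc) {
    t0 <- tryCatch(uniroot(gfun, c(tt[i], tt[i + 1]), tol = tol)$root,
                   error = function(e) NA_real_)
    if (is.na(t0)) next
    d <- sum((spec$curve(t0) - r)^2)
    if (d < best_d) { best_d <- d; best_t <- t0 }
  }
  if (is.na(best_t)) best_t <- tt[which.min(dist2)]
  best_t
}

#' Local orthonormal frame of the fiber construction
#'
#' At a point `r`, returns the layer normal `n_hat = grad f / ||grad f||`,
#' the curve tangent `k_hat` at the nearest perpendicular foot, and the
#' in-layer tangents `t1_hat` (meridional, oriented fundus-to-cervix, i.e.
#' with positive projection on `k_hat`) and `t2_hat = t1_hat x n_hat`
#' (circumferential). `t1_hat = beta k_hat + gamma n_hat` with
#' `beta = 1/sqrt(1 - <k,n>^2)`, `gamma = -beta <k,n>`.
#'
#' @param r length-3 position (m)
#' @param spec a [fiber_spec()]
#' @return list with `n_hat`, `t1_hat`, `t2_hat`, `k_hat`, `t0` (foot
#'   parameter), and `singular = TRUE` at pole points (where the frame is
#'   undefined and callers should use a zero fiber)
#' @export
local_frame <- function(r, spec) {
  r <- as.numeric(r)
  g <- if (is.null(spec$grad_f)) grad_numeric(spec$f, r) else spec$grad_f(r)
  g <- as.numeric(g)
  gn <- sqrt(sum(g^2))
  if (gn == 0) stop("local_frame: gradient of f vanishes at r")
  n_hat <- g / gn
  t0 <- nearest_foot(spec, r)
  h <- diff(spec$t_range) * 1e-7
  k <- (spec$curve(min(t0 + h, spec$t_range[2])) -
        spec$curve(max(t0 - h, spec$t_range[1])))
  k_hat <- k / sqrt(sum(k^2))
  kn <- sum(k_hat * n_hat)
  if (abs(kn) >= 1 - 1e-12)
    return(list(n_hat = n_hat, k_hat = k_hat, t0 = t0, singular = TRUE))
  beta <- 1 / sqrt(1 - kn^2)          # branch: <t1, k> = beta (1 - kn^2) > 0
  gamma <- -beta * kn
  t1 <- beta * k_hat + gamma * n_hat
  t2 <- c(t1[2] * n_hat[3] - t1[3] * n_hat[2],
          t1[3] * n_hat[1] - t1[1] * n_hat[3],
          t1[1] * n_hat[2] - t1[2] * n_hat[1])
  list(n_hat = n_hat, t1_hat = t1, t2_hat = t2, k_hat = k_hat,
       t0 = t0, singular = FALSE)
}

#' Fiber direction from the general frame construction
#'
#' `a3 = t1_hat cos(alpha) + t2_hat sin(alpha)`; the zero vector at singular
#' (pole) points.
#'
#' @param r n x 3 matrix (or length-3 vector) of positions
#' @param spec a [fiber_spec()]
#' @return n x 3 matrix of unit (or zero) fiber directions
#' @export
fiber_direction <- function(r, spec) {
  r <- as_points3(r)
  al <- spec$alpha(r)
  out <- matrix(0, nrow(r), 3)
  for (i in seq_len(nrow(r))) {
    fr <- local_frame(r[i, ], spec)
    if (isTRUE(fr$singular)) next
    out[i, ] <- fr$t1_hat * cos(al[i]) + fr$t2_hat * sin(al[i])
  }
  out
}

#' Closed-form fiber direction on a spherical layer
#'
#' For spherical layers about the origin with the z axis as curve of symmetry
#' (fundus at +z), the frame construction reduces to
#' \deqn{a_3 = \left(\frac{zx\cos\alpha}{Rs} + \frac{y\sin\alpha}{s},\;
#'   \frac{zy\cos\alpha}{Rs} - \frac{x\sin\alpha}{s},\;
#'   -\frac{s\cos\alpha}{R}\right), \quad s = \sqrt{x^2+y^2},\; R = \|r\|.}
#' On the z axis (s = 0) the direction is the zero vector (isotropic point).
#'
#' @param r n x 3 matrix (or length-3 vector) of positions
#' @param alpha orientation angle (rad), scalar or length-n
#' @return n x 3 matrix of fiber directions
#' @export
#' @examples
#' spherical_fiber_direction(c(0.16, 0, 0), 0)       # (0, 0, -1): meridional
#' spherical_fiber_direction(c(0, 0.16, 0), pi / 2)  # (1, 0, 0): circumferential
spherical_fiber_direction <- function(r, alpha = 0) {
  r <- as_points3(r)
  R <- sqrt(rowSums(r^2))
  s <- sqrt(r[, 1]^2 + r[, 2]^2)
  ca <- cos(alpha); sa <- sin(alpha)
  ok <- s > 1e-14 * pmax(R, 1e-300)
  out <- matrix(0, nrow(r), 3)
  x <- r[ok, 1]; y <- r[ok, 2]; z <- r[ok, 3]
  Rk <- R[ok]; sk <- s[ok]
  if (length(ca) > 1) { ca <- ca[ok]; sa <- sa[ok] }
  out[ok, 1] <- z * x * ca / (Rk * sk) + y * sa / sk
  out[ok, 2] <- z * y * ca / (Rk * sk) - x * sa / sk
  out[ok, 3] <- -sk * ca / Rk
  out
}

#' Fiber direction via the axis-aligned matrix construction
#'
#' When the curve of symmetry is parallel to the z axis, the frame reduces to
#' `a3 = (P cos(alpha) + F sin(alpha)) n_hat` with
#' `P = diag(a, a, -1/a)`, `a = grad_z f / sqrt(grad_x f^2 + grad_y f^2)`,
#' and `F` the antisymmetric matrix with `F[1,2] = b = ||grad f|| /
#' sqrt(grad_x f^2 + grad_y f^2)`. Points with
#' `grad_x f = grad_y f = 0` (the axis) return the zero vector.
#'
#' @param r n x 3 matrix (or length-3 vector) of positions
#' @param f implicit layer function (vectorised)
#' @param alpha orientation angle (rad)
#' @param grad_f optional analytic gradient
#' @return n x 3 matrix of fiber directions
#' @export
axis_aligned_fiber_direction <- function(r, f, alpha = 0, grad_f = NULL) {
  r <- as_points3(r)
  g <- if (is.null(grad_f)) grad_numeric(f, r) else grad_f(r)
  gn <- sqrt(rowSums(g^2))
  n_hat <- g / gn
  sxy <- sqrt(n_hat[, 1]^2 + n_hat[, 2]^2)
  ok <- sxy > 1e-12
  out <- matrix(0, nrow(r), 3)
  a <- n_hat[ok, 3] / sxy[ok]
  b <- 1 / sxy[ok]
  ca <- cos(alpha); sa <- sin(alpha)
  nx <- n_hat[ok, 1]; ny <- n_hat[ok, 2]
  # P n = (a nx, a ny, -nz / a); F n = (b ny, -b nx, 0).
  # For a unit normal, -nz / a = -sqrt(nx^2 + ny^2), which is also the
  # correct limit on the equator where a = 0.
  out[ok, 1] <- ca * a * nx + sa * b * ny
  out[ok, 2] <- ca * a * ny - sa * b * nx
  out[ok, 3] <- -ca * sxy[ok]
  out
}
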