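#' Myocyte packing geometry
#'
#' Dimensions of the idealised cylindrical myocyte and of the cubical-grid
#' unit cell used for the extracellular conductivity estimates. The unit
#' cell has cross-section side `d_T = d_cell + 2 * delta_e` and length
#' `l_T = l_cell + 2 * delta_e`, where `delta_e` is half the extracellular
#' gap between neighbouring cells. Defaults are the term-pregnancy myocyte
#' (7 um x 450 um, 0.5 um gap half-spacing).
#'
#' @param d_cell myocyte diameter (m)
#' @param l_cell myocyte length (m)
#' @param delta_e extracellular gap half-spacing (m)
#' @return a `myocyte_geometry` object with derived `d_T`, `l_T`
#' @export
myocyte_geometry <- function(d_cell = 7e-6, l_cell = 450e-6, delta_e = 0.5e-6) {
  if (d_cell <= 0 || l_cell <= 0 || delta_e < 0)
    stop("myocyte_geometry: dimensions must be positive")
  if (l_cell / d_cell < 10)
    warning("myocyte_geometry: l_cell/d_cell < 10; the long-cylinder ",
            "assumption is questionable")
  structure(list(d_cell = d_cell, l_cell = l_cell, delta_e = delta_e,
                 d_T = d_cell + 2 * delta_e, l_T = l_cell + 2 * delta_e),
            class = "myocyte_geometry")
}

#' Archie's-law extracellular conductivity
#'
#' Bulk tissue of conductivity `sigma_M` containing insulating inclusions of
#' volume fraction `p` implies an extracellular-medium conductivity
#' \eqn{\tilde\sigma_e = \sigma_M / (1-p)^m}, with cementation factor `m`
#' set by inclusion shape and orientation (4/3 for long cylinders).
#'
#' @param sigma_M effective bulk myometrium conductivity (S/m)
#' @param p volume fraction of myocytes plus collagenous fibers
#' @param m cementation factor
#' @return extracellular conductivity (S/m)
#' @export
#' @examples
#' archie_extracellular(0.5, 0.6, 4/3)  # ~1.697 S/m
archie_extracellular <- function(sigma_M = 0.5, p = 0.6, m = 4/3) {
  if (sigma_M <= 0) stop("archie_extracellular: sigma_M must be > 0")
  if (m <= 0) stop("archie_extracellular: m must be > 0")
  if (p < 0 || p >= 1)
    stop("archie_extracellular: volume fraction p must satisfy 0 <= p < 1")
  sigma_M / (1 - p)^m
}

#' Longitudinal and transverse extracellular conductivities (grid model)
#'
#' Myocytes arranged on a cubical grid restrict the extracellular current by
#' the occluded area fraction: along the fiber the cylinders block
#' \eqn{\pi d_{cell}^2 / (4 d_T^2)} of the cross-section, across the fiber a
#' \eqn{d_{cell} l_{cell} / (d_T l_T)} fraction, giving
#' \deqn{\sigma_{el} = \tilde\sigma_e (1 - \pi d_{cell}^2/(4 d_T^2)), \quad
#'       \sigma_{et} = \tilde\sigma_e (1 - d_{cell} l_{cell}/(d_T l_T)).}
#'
#' @param sigma_e_tilde extracellular medium conductivity (S/m), e.g. from
#'   [archie_extracellular()]
#' @param geom a [myocyte_geometry()]
#' @return named vector `c(sigma_el, sigma_et)` (S/m)
#' @export
#' @examples
#' grid_conductivities(archie_extracellular(), myocyte_geometry())
#' # sigma_el ~ 0.68, sigma_et ~ 0.22 S/m
grid_conductivities <- function(sigma_e_tilde, geom = myocyte_geometry()) {
  fa <- pi * geom$d_cell^2 / (4 * geom$d_T^2)
  fl <- geom$d_cell * geom$l_cell / (geom$d_T * geom$l_T)
  if (fa >= 1 || fl >= 1)
    stop("grid_conductivities: occluded fraction >= 1; cells overlap")
  c(sigma_el = sigma_e_tilde * (1 - fa), sigma_et = sigma_e_tilde * (1 - fl))
}

# x / (1 - x), the anisotropy-ratio map; domain x < 1
g_ratio <- function(x) {
  if (any(x >= 1)) stop("g_ratio: argument must be < 1")
  x / (1 - x)
}

#' Admissible interval for the edge-sharpness constant
#'
#' The equal-anisotropy ratio is nonnegative only if
#' \eqn{0 < \varepsilon_1 < \sigma_{el} k \Delta^2 / (2 c^2 a_m c_m^2)}
#' with \eqn{\Delta = v_1^* - 2 v_2^* + v_3^*}; this returns the upper bound.
#'
#' @param c_speed target propagation speed (m/s)
#' @param params an [ionic_params()]
#' @param sigma_el longitudinal extracellular conductivity (S/m)
#' @param roots optional cubic roots from [nullcline_fixed_points()]
#' @return upper bound on `eps1` (Ohm m^2)
#' @export
eps1_upper_bound <- function(c_speed, params, sigma_el, roots = NULL) {
  if (is.null(roots)) roots <- nullcline_fixed_points(params)
  delta <- roots[1] - 2 * roots[2] + roots[3]
  sigma_el * params$k * delta^2 / (2 * c_speed^2 * params$a_m * params$c_m^2)
}

#' Equal-anisotropy ratio from a target propagation speed
#'
#' Calibrates the ratio \eqn{\varsigma} in \eqn{G_i' = \varsigma G_e'} so the
#' plane-wave front of the monodomain equation travels at speed `c_speed`
#' along the fiber. The closed form follows from the traveling-wave ansatz
#' \eqn{v_m(\xi\cdot r - ct)} applied to the monodomain cubic with the
#' recovery variable frozen at rest: the bistable front speed is
#' \eqn{c = \sqrt{K D / 2}\,(v_1^*-2v_2^*+v_3^*)} with reaction rate
#' \eqn{K = k/(\varepsilon_1 c_m)} and diffusivity
#' \eqn{D = \frac{\varsigma}{1+\varsigma}\,\sigma_{el}/(a_m c_m)}, giving
#' \deqn{\varsigma = g\!\left(\frac{2 c^2 \varepsilon_1 a_m c_m^2}
#'       {\sigma_{el} k (v_1^*-2v_2^*+v_3^*)^2}\right), \qquad g(x)=\frac{x}{1-x}.}
#' The argument must be below 1 (equivalently `eps1` below
#' [eps1_upper_bound()]); otherwise no nonnegative ratio can reach the
#' requested speed and a calibration error reports the admissible interval.
#'
#' The closed form assumes the recovery variable does not move on the front
#' time-scale; [calibrate_varsigma_numeric()] provides the direct
#' speed-matching alternative on a simulated cable.
#'
#' @inheritParams eps1_upper_bound
#' @return the anisotropy ratio (dimensionless, >= 0)
#' @export
anisotropy_ratio <- function(c_speed, params, sigma_el, roots = NULL) {
  if (is.null(roots)) roots <- nullcline_fixed_points(params)
  delta <- roots[1] - 2 * roots[2] + roots[3]
  x <- 2 * c_speed^2 * params$eps1 * params$a_m * params$c_m^2 /
    (sigma_el * params$k * delta^2)
  if (x >= 1) {
    bound <- eps1_upper_bound(c_speed, params, sigma_el, roots)
    stop("anisotropy_ratio: eps1 = ", params$eps1,
         " outside the admissible interval (0, ", signif(bound, 6),
         ") for target speed ", c_speed,
         " m/s; no nonnegative anisotropy ratio reaches this speed")
  }
  g_ratio(x)
}

#' Plane-wave front speed predicted for a given anisotropy ratio
#'
#' Inverse of [anisotropy_ratio()]: the frozen-recovery front speed
#' \eqn{c = \sqrt{K D/2}\,\Delta}.
#'
#' @param varsigma equal-anisotropy ratio
#' @inheritParams eps1_upper_bound
#' @return speed (m/s)
#' @export
front_speed_closed_form <- function(varsigma, params, sigma_el, roots = NULL) {
  if (is.null(roots)) roots <- nullcline_fixed_points(params)
  delta <- roots[1] - 2 * roots[2] + roots[3]
  D <- (varsigma / (1 + varsigma)) * sigma_el / (params$a_m * params$c_m)
  K <- params$k / (params$eps1 * params$c_m)
  sqrt(K * D / 2) * abs(delta)
}

#' Numerical speed-matching calibration of the anisotropy ratio
#'
#' Bisects the anisotropy ratio so that the measured front speed of a 1D
#' monodomain cable simulation matches `c_speed`. This is the independent
#' oracle for [anisotropy_ratio()]; it makes no frozen-recovery assumption.
#'
#' @inheritParams eps1_upper_bound
#' @param sigma_et transverse conductivity (unused by the 1D cable, kept for
#'   interface symmetry)
#' @param cable_length,resolution,dt cable discretisation controls
#' @param interval search interval for the ratio
#' @param tol relative bisection tolerance on the ratio
#' @return list with `varsigma`, `speed` (m/s) achieved, `target`
#' @export
calibrate_varsigma_numeric <- function(c_speed, params, sigma_el,
                                       sigma_et = NULL,
                                       cable_length = 0.2, resolution = 1e-3,
                                       dt = 0.01, interval = c(1e-3, 50),
                                       tol = 1e-3) {
  measure <- function(vs) {
    sim <- simulate_cable(params, sigma_el, vs, length = cable_length,
                          resolution = resolution, dt = dt)
    sim$speed
  }
  f_lo <- measure(interval[1]) - c_speed
  f_hi <- measure(interval[2]) - c_speed
  if (f_lo * f_hi > 0)
    stop("calibrate_varsigma_numeric: target speed ", c_speed,
         " m/s not bracketed by ratios in [", interval[1], ", ", interval[2],
         "] (speeds ", signif(f_lo + c_speed, 4), " to ",
         signif(f_hi + c_speed, 4), " m/s)")
  lo <- interval[1]; hi <- interval[2]
  while ((hi - lo) / hi > tol) {
    mid <- sqrt(lo * hi)
    if ((measure(mid) - c_speed) * f_lo <= 0) hi <- mid else lo <- mid
  }
  vs <- sqrt(lo * hi)
  list(varsigma = vs, speed = measure(vs), target = c_speed)
}

#' Conductivity model of the volume conductor
#'
#' Bundles the compartment conductivities, the Archie/grid-derived
#' extracellular values and the equal-anisotropy ratio. With
#' `derive = TRUE` (default), `sigma_e_tilde`, `sigma_el` and `sigma_et`
#' are computed from `sigma_M`, `p`, `m` and the myocyte geometry; the
#' intracellular values are `sigma_il = varsigma * sigma_el`,
#' `sigma_it = varsigma * sigma_et`.
#'
#' @param sigma_M bulk myometrium conductivity (S/m)
#' @param p myocyte volume fraction
#' @param m cementation factor
#' @param geom a [myocyte_geometry()]
#' @param varsigma equal-anisotropy ratio; the published example value 0.8
#' @param G_A,G_U,G_F abdominal, amniotic-fluid and fetal conductivities
#'   (S/m)
#' @param derive derive the sigma chain (otherwise supply `sigma_el`,
#'   `sigma_et` directly)
#' @param sigma_el,sigma_et explicit values when `derive = FALSE`
#' @return a `conductivity_model` object
#' @export
#' @examples
#' cm <- conductivity_model()
#' c(cm$sigma_el, cm$sigma_et, cm$varsigma)  # 0.68, 0.22, 0.8
conductivity_model <- function(sigma_M = 0.5, p = 0.6, m = 4/3,
                               geom = myocyte_geometry(), varsigma = 0.8,
                               G_A = 0.2, G_U = 1.74, G_F = 0.2,
                               derive = TRUE, sigma_el = NULL, sigma_et = NULL) {
  if (derive) {
    sigma_e_tilde <- archie_extracellular(sigma_M, p, m)
    se <- grid_conductivities(sigma_e_tilde, geom)
    sigma_el <- unname(se["sigma_el"]); sigma_et <- unname(se["sigma_et"])
  } else {
    sigma_e_tilde <- NA_real_
    if (is.null(sigma_el) || is.null(sigma_et))
      stop("conductivity_model: supply sigma_el and sigma_et when derive = FALSE")
  }
  if (varsigma < 0) stop("conductivity_model: varsigma must be >= 0")
  if (any(c(sigma_el, sigma_et, G_A, G_U, G_F) <= 0))
    stop("conductivity_model: conductivities must be > 0")
  if (sigma_el <= sigma_et)
    stop("conductivity_model: sigma_el > sigma_et violated (",
         sigma_el, " <= ", sigma_et, ")")
  structure(list(sigma_M = sigma_M, p = p, m = m, geom = geom,
                 sigma_e_tilde = sigma_e_tilde,
                 sigma_el = sigma_el, sigma_et = sigma_et,
                 varsigma = varsigma,
                 sigma_il = varsigma * sigma_el, sigma_it = varsigma * sigma_et,
                 G_A = G_A, G_U = G_U, G_F = G_F),
            class = "conductivity_model")
}

#' @export
print.conductivity_model <- function(x, ...) {
  cat("Volume-conductor conductivities (S/m)\n")
  cat(sprintf("  compartments: G_A = %g, G_U = %g, G_F = %g\n", x$G_A, x$G_U, x$G_F))
  cat(sprintf("  extracellular medium sigma_e~ = %s\n",
              if (is.na(x$sigma_e_tilde)) "(not derived)" else signif(x$sigma_e_tilde, 4)))
  cat(sprintf("  myometrium: sigma_el = %.4g, sigma_et = %.4g, varsigma = %g\n",
              x$sigma_el, x$sigma_et, x$varsigma))
  cat(sprintf("  intracellular: sigma_il = %.4g, sigma_it = %.4g\n",
              x$sigma_il, x$sigma_it))
  invisible(x)
}

#' Cylindrically symmetric conductivity tensor field
#'
#' Given a fiber direction field `fiber(r)` (unit vectors, or zero at
#' isotropic points) and longitudinal/transverse conductivities, builds the
#' tensor field
#' \deqn{G'(r) = (\sigma_l - \sigma_t)\, a_3(r) a_3(r)^T + \sigma_t I_3,}
#' which has eigenvalues \eqn{(\sigma_t, \sigma_t, \sigma_l)} where the fiber
#' is defined and reduces to \eqn{\sigma_t I} at isotropic points
#' (\eqn{a_3 = 0}).
#'
#' @param fiber function mapping an n x 3 position matrix to an n x 3 matrix
#'   of fiber directions with row norms 0 or 1
#' @param sigma_l,sigma_t longitudinal and transverse conductivities (S/m)
#' @return a `tensor_field` object: a function `field(r)` returning a
#'   3 x 3 x n array, with attributes `sigma_l`, `sigma_t`, `fiber`
#' @export
assemble_tensor_field <- function(fiber, sigma_l, sigma_t) {
  if (sigma_l <= 0 || sigma_t <= 0)
    stop("assemble_tensor_field: conductivities must be > 0")
  force(fiber)
  field <- function(r) {
    r <- as_points3(r)
    a <- as_points3(fiber(r))
    nrm <- sqrt(rowSums(a^2))
    bad <- abs(nrm) > 1e-8 & abs(nrm - 1) > 1e-8
    if (any(bad))
      stop("tensor_field: fiber direction must be unit or zero; got norm ",
           signif(nrm[which(bad)[1]], 6), " at row ", which(bad)[1])
    n <- nrow(r)
    out <- array(0, c(3, 3, n))
    ds <- sigma_l - sigma_t
    for (i in 1:3) for (j in 1:3) {
      out[i, j, ] <- ds * a[, i] * a[, j] + if (i == j) sigma_t else 0
    }
    out
  }
  structure(field, class = "tensor_field",
            sigma_l = sigma_l, sigma_t = sigma_t, fiber = fiber)
}

#' Isotropic tensor field
#' @param sigma conductivity (S/m)
#' @return a `tensor_field` returning `sigma * I3` everywhere
#' @export
isotropic_tensor_field <- function(sigma) {
  assemble_tensor_field(function(r) matrix(0, nrow(as_points3(r)), 3),
                        sigma_l = sigma, sigma_t = sigma)
}
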