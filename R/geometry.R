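#' Four-compartment spherical volume-conductor geometry
#'
#' Configuration of the concentric fetus (F), intrauterine cavity (U) and
#' myometrial shell (M), enclosed by an abdominal sphere (A) whose centre may
#' be shifted so that the uterus sits closer to the ventral surface. All
#' lengths in metres; the origin is the myometrial centre. Defaults are the
#' term-pregnancy example: 16 cm outer myometrial radius, 1 cm wall, 12 cm
#' fetal sphere, 21 cm abdomen shifted -3 cm along x, and an insulating
#' vernix caseosa layer on the fetal surface (`lambda_vernix = 0`).
#'
#' @param r_myo_outer outer myometrial radius, centre to the perimetrium
#'   surface (m)
#' @param wall_thickness uterine wall thickness (m)
#' @param r_fetus fetal sphere radius (m)
#' @param r_abdomen abdominal sphere radius (m)
#' @param abdomen_offset length-3 displacement of the abdominal centre (m)
#' @param lambda_vernix vernix caseosa switch: 0 = fetal boundary insulated
#'   (vernix present), nonzero = conductive fetal compartment
#' @return a `geometry_config` object
#' @export
geometry_config <- function(r_myo_outer = 0.16, wall_thickness = 0.01,
                            r_fetus = 0.12, r_abdomen = 0.21,
                            abdomen_offset = c(-0.03, 0, 0),
                            lambda_vernix = 0) {
  cfg <- list(r_myo_outer = r_myo_outer, wall_thickness = wall_thickness,
              r_fetus = r_fetus, r_abdomen = r_abdomen,
              abdomen_offset = as.numeric(abdomen_offset),
              lambda_vernix = lambda_vernix)
  if (length(cfg$abdomen_offset) != 3L)
    stop("geometry_config: abdomen_offset must have length 3")
  if (wall_thickness <= 0)
    stop("geometry_config: wall_thickness > 0 violated")
  r_inner <- r_myo_outer - wall_thickness
  if (!(r_fetus < r_inner))
    stop("geometry_config: r_fetus < r_myo_outer - wall_thickness violated (",
         r_fetus, " >= ", r_inner, ")")
  if (!(r_inner < r_myo_outer))
    stop("geometry_config: wall inner radius must be below outer radius")
  # the abdominal sphere must enclose the whole uterus
  if (sqrt(sum(cfg$abdomen_offset^2)) + r_myo_outer >= r_abdomen)
    stop("geometry_config: myometrium pierces abdomen: ",
         "||abdomen_offset|| + r_myo_outer < r_abdomen violated (",
         sqrt(sum(cfg$abdomen_offset^2)) + r_myo_outer, " >= ", r_abdomen, ")")
  structure(cfg, class = "geometry_config")
}

#' Implicit-surface description of the four compartments
#'
#' Builds signed-distance-style classifiers for the compartments F, U, M, A
#' and their interfaces from a validated [geometry_config()]. Points are
#' classified by radius from the myometrial centre (F/U/M) and from the
#' shifted abdominal centre (A).
#'
#' @param config a [geometry_config()]
#' @return a `uw_geometry` object with elements:
#'   \describe{
#'     \item{config}{the input configuration}
#'     \item{compartment_of}{function(points) -> factor in F, U, M, A
#'       (NA outside the abdomen)}
#'     \item{sdf}{named list of signed-distance functions (negative inside)
#'       for the fetal, uterine-cavity, myometrial and abdominal spheres}
#'     \item{interface_radius}{named radii of the spherical interfaces dF,
#'       dU, dM (about the origin) and dA (about the abdominal centre)}
#'     \item{outer_radius}{function(u) giving, for unit directions u from the
#'       origin, the distance to the abdominal surface along u}
#'   }
#' @export
#' @examples
#' g <- build_spherical_geometry(geometry_config())
#' g$compartment_of(rbind(c(0, 0, 0), c(0.155, 0, 0)))  # F, M
build_spherical_geometry <- function(config) {
  if (!inherits(config, "geometry_config"))
    config <- do.call(geometry_config, as.list(config))
  rf <- config$r_fetus
  ru <- config$r_myo_outer - config$wall_thickness
  rm_ <- config$r_myo_outer
  ra <- config$r_abdomen
  ca <- config$abdomen_offset

  radius0 <- function(p) sqrt(rowSums(as_points3(p)^2))
  radiusA <- function(p) {
    p <- as_points3(p)
    sqrt(rowSums(sweep(p, 2, ca)^2))
  }
  compartment_of <- function(points) {
    r0 <- radius0(points); rA <- radiusA(points)
    out <- rep(NA_character_, length(r0))
    out[rA <= ra] <- "A"
    out[r0 <= rm_] <- "M"
    out[r0 <= ru] <- "U"
    out[r0 <= rf] <- "F"
    factor(out, levels = c("F", "U", "M", "A"))
  }
  outer_radius <- function(u) {
    # distance t >= 0 with ||t u - ca|| = ra along unit direction u from origin
    u <- as_points3(u)
    uc <- drop(u %*% ca)
    uc + sqrt(uc^2 + ra^2 - sum(ca^2))
  }
  structure(list(
    config = config,
    compartment_of = compartment_of,
    sdf = list(F = function(p) radius0(p) - rf,
               U = function(p) radius0(p) - ru,
               M = function(p) radius0(p) - rm_,
               A = function(p) radiusA(p) - ra),
    interface_radius = c(dF = rf, dU = ru, dM = rm_, dA = ra),
    outer_radius = outer_radius
  ), class = "uw_geometry")
}

#' @export
print.uw_geometry <- function(x, ...) {
  cfg <- x$config
  cat("Four-compartment spherical volume conductor\n")
  cat(sprintf("  fetus F: r <= %g m | cavity U: r <= %g m | myometrium M: r <= %g m\n",
              cfg$r_fetus, cfg$r_myo_outer - cfg$wall_thickness, cfg$r_myo_outer))
  cat(sprintf("  abdomen A: radius %g m about (%g, %g, %g)\n",
              cfg$r_abdomen, cfg$abdomen_offset[1], cfg$abdomen_offset[2],
              cfg$abdomen_offset[3]))
  cat(sprintf("  vernix lambda = %g (%s fetal boundary)\n", cfg$lambda_vernix,
              if (cfg$lambda_vernix == 0) "insulated" else "conductive"))
  invisible(x)
}

# integer codes used on meshes for compartments and interfaces
COMPARTMENT_CODES <- c(F = 1L, U = 2L, M = 3L, A = 4L)
BOUNDARY_CODES <- c(none = 0L, dF = 1L, dU = 2L, dM = 3L, dA = 4L)

#' Compartment label codes
#'
#' Meshes store compartment and boundary labels as integers; these helpers
#' map between codes and names (`F`, `U`, `M`, `A`; `dF`, `dU`, `dM`, `dA`).
#'
#' @param x integer codes or character names
#' @return the corresponding names or codes
#' @export
compartment_name <- function(x) names(COMPARTMENT_CODES)[match(x, COMPARTMENT_CODES)]

#' @rdname compartment_name
#' @export
compartment_code <- function(x) unname(COMPARTMENT_CODES[match(x, names(COMPARTMENT_CODES))])

#' @rdname compartment_name
#' @export
boundary_code <- function(x) unname(BOUNDARY_CODES[match(x, names(BOUNDARY_CODES))])
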