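# ---------------------------------------------------------------------------
# Config-driven orchestration of the three-step forward procedure:
#   Step 1  monodomain solve for v_m on the myometrium
#   Step 2  volume-conductor solve for the potentials (abdominal EMG)
#   Step 3  Biot-Savart magnetic field at the sensors (MMG)
# followed by summary metrics, with a JSON run manifest for reproducibility.
# ---------------------------------------------------------------------------

#' Assemble a run configuration
#'
#' A flat, typed configuration mirroring the published parameter tables:
#' geometry (compartment radii), ionic constants, myocyte dimensions and
#' Archie parameters, compartment conductivities, pacemakers, solver
#' controls. SI units throughout.
#'
#' @param geometry list of [geometry_config()] arguments
#' @param ionic list of [ionic_params()] arguments
#' @param myocyte list of [myocyte_geometry()] arguments
#' @param conductivity list of [conductivity_model()] arguments (without
#'   `geom`, taken from `myocyte`)
#' @param alpha fiber orientation angle (rad); default 45 degrees
#' @param c_target reference propagation speed for calibration (m/s)
#' @param pacemakers list of pacemaker descriptions; each a list with `nu`,
#'   `t_on`, `t_off`, `r_min`, `r_max`, `z_min` (see [fundus_pacemaker()])
#' @param solver list of [solver_config()] arguments (`dt`, `t_end`,
#'   `output_stride`, ...)
#' @param mesh list with `resolution` (m), `dimension`, optional
#'   `min_wall_layers`
#' @param sensors list with `nsub`, `cap_axis`, `cap_angle` for
#'   [abdominal_sensor_array()], or a `file` path of a sensor CSV
#' @param probe_elevation polar angles (rad, from +z) of myometrial probes
#'   for waveform traces
#' @param seed integer seed recorded in the manifest
#' @param out_dir output directory for [run_pipeline()]
#' @return a `run_config` object
#' @export
run_config <- function(geometry = list(), ionic = list(), myocyte = list(),
                       conductivity = list(), alpha = pi / 4,
                       c_target = 0.0115,
                       pacemakers = list(list(nu = 2, t_on = 0, t_off = 0.1,
                                              r_min = 0.15, r_max = 0.16,
                                              z_min = 0.15)),
                       solver = list(dt = 0.02, t_end = 120,
                                     output_stride = 50L),
                       mesh = list(resolution = 0.03, dimension = 3L),
                       sensors = list(nsub = 2L, cap_axis = c(1, 0, 0),
                                      cap_angle = pi),
                       probe_elevation = c(0.4, 0.9, 1.4) * pi / 2,
                       seed = 1L, out_dir = "uterowave_run") {
  cfg <- list(geometry = geometry, ionic = ionic, myocyte = myocyte,
              conductivity = conductivity, alpha = alpha,
              c_target = c_target, pacemakers = pacemakers, solver = solver,
              mesh = mesh, sensors = sensors,
              probe_elevation = probe_elevation,
              seed = as.integer(seed), out_dir = out_dir)
  # validate eagerly: every sub-config must construct
  geom_cfg <- do.call(geometry_config, cfg$geometry)
  do.call(ionic_params, cfg$ionic)
  do.call(myocyte_geometry, cfg$myocyte)
  if (!is.null(cfg$sensors$file) && !file.exists(cfg$sensors$file))
    stop("run_config: sensor file not found: ", cfg$sensors$file)
  cfg$geometry <- unclass(geom_cfg)
  structure(cfg, class = "run_config")
}

#' Read / write run configurations as YAML
#' @param file path
#' @return a [run_config()]
#' @export
read_run_config <- function(file) {
  raw <- yaml::read_yaml(file)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config a [run_config()]
#' @export
write_run_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' Derive the conductivity chain of the configuration
#'
#' Runs the Archie's-law and grid-model chain from the myocyte table, then
#' calibrates the equal-anisotropy ratio from the configured target speed
#' (closed form; errors with the admissible eps1 interval if the target
#' speed is unreachable, see [anisotropy_ratio()]).
#'
#' @param config a [run_config()]
#' @param verbose print the intermediate values
#' @return a [conductivity_model()] with `varsigma` from the calibration
#' @export
calibrate <- function(config, verbose = TRUE) {
  geom <- do.call(myocyte_geometry, config$myocyte)
  cc <- config$conductivity
  sigma_M <- cc$sigma_M %||% 0.5
  p <- cc$p %||% 0.6
  m <- cc$m %||% (4 / 3)
  se_t <- archie_extracellular(sigma_M, p, m)
  se <- grid_conductivities(se_t, geom)
  params <- do.call(ionic_params, config$ionic)
  roots <- nullcline_fixed_points(params)
  if (verbose) {
    cat(sprintf("sigma_e~ = %.4f S/m (Archie: sigma_M = %g, p = %g, m = %g)\n",
                se_t, sigma_M, p, m))
    cat(sprintf("sigma_el = %.4f, sigma_et = %.4f S/m (grid model)\n",
                se["sigma_el"], se["sigma_et"]))
    cat(sprintf("frozen-recovery cubic roots: %.4f, %.4f, %.4f V\n",
                roots[1], roots[2], roots[3]))
  }
  vs <- anisotropy_ratio(config$c_target, params, unname(se["sigma_el"]),
                         roots)
  if (verbose) cat(sprintf("varsigma = %.4f (target speed %g m/s)\n",
                           vs, config$c_target))
  conductivity_model(sigma_M = sigma_M, p = p, m = m, geom = geom,
                     varsigma = vs,
                     G_A = cc$G_A %||% 0.2, G_U = cc$G_U %||% 1.74,
                     G_F = cc$G_F %||% 0.2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full three-step forward pipeline
#'
#' Builds geometry, meshes and conductivity tensors, solves the monodomain
#' equation for the transmembrane potential (Step 1), the volume-conductor
#' problem for the potentials at the stored snapshot times (Step 2), and
#' the abdominal magnetic field at the sensor array (Step 3); computes
#' waveform and contracting-fraction metrics and writes meshes (VTK),
#' traces/metrics (CSV) and a JSON manifest into the run directory.
#' Deterministic: re-running an identical configuration reproduces all
#' output files.
#'
#' @param config a [run_config()]
#' @param out_dir output directory (default from the config)
#' @return (invisibly) a list with the in-memory results: meshes, series,
#'   sensor traces, metrics, manifest
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  t_start <- Sys.time()
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage <- "setup"
  wall <- list()
  res <- list()
  tic <- function() Sys.time()
  toc <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))
  run_stage <- function(name, expr) {
    stage <<- name
    t0 <- tic()
    out <- tryCatch(force(expr), error = function(e)
      stop("run_pipeline: stage '", name, "' failed: ", conditionMessage(e),
           "; completed artifacts in ", normalizePath(out_dir),
           call. = FALSE))
    wall[[name]] <<- toc(t0)
    out
  }

  geom <- run_stage("geometry", {
    build_spherical_geometry(do.call(geometry_config, config$geometry))
  })
  params <- do.call(ionic_params, config$ionic)
  lambda <- config$geometry$lambda_vernix %||% 0

  full_mesh <- run_stage("mesh", {
    comps <- if (lambda == 0) c("U", "M", "A") else c("F", "U", "M", "A")
    generate_mesh(geom, resolution = config$mesh$resolution,
                  dimension = config$mesh$dimension %||% 3L,
                  compartments = comps,
                  min_wall_layers = config$mesh$min_wall_layers %||% 2L)
  })
  subM <- submesh(full_mesh, "M")

  cond <- run_stage("conductivity", {
    geo_my <- do.call(myocyte_geometry, config$myocyte)
    cc <- config$conductivity
    conductivity_model(sigma_M = cc$sigma_M %||% 0.5, p = cc$p %||% 0.6,
                       m = cc$m %||% (4 / 3), geom = geo_my,
                       varsigma = cc$varsigma %||% 0.8,
                       G_A = cc$G_A %||% 0.2, G_U = cc$G_U %||% 1.74,
                       G_F = cc$G_F %||% 0.2)
  })
  fiber <- function(r) spherical_fiber_direction(r, config$alpha)
  tf <- assemble_tensor_field(fiber, cond$sigma_el, cond$sigma_et)

  pacemakers <- lapply(config$pacemakers, function(pm)
    fundus_pacemaker(nu = pm$nu %||% 2, t_on = pm$t_on %||% 0,
                     t_off = pm$t_off %||% 0.1, r_min = pm$r_min %||% 0.15,
                     r_max = pm$r_max %||% 0.16, z_min = pm$z_min %||% 0.15))

  step1 <- run_stage("monodomain", {
    ops <- assemble_operators(subM$mesh, tf, cond$varsigma, params)
    cfg <- do.call(solver_config, config$solver)
    run_monodomain(subM$mesh, ops, params, pacemakers, cfg)
  })
  vm <- step1$v_m

  phi <- run_stage("potentials", {
    # lift v_m to the full mesh through the node map
    V <- matrix(0, nrow(full_mesh$nodes), length(vm$times))
    V[subM$node_map, ] <- vm$values
    lifted <- field_series(vm$times, V, full_mesh, "v_m", "V")
    solve_potential_series(full_mesh, lifted, cond, tf, lambda)
  })

  sensors <- run_stage("sensors", {
    if (!is.null(config$sensors$file)) read_sensor_csv(config$sensors$file)
    else abdominal_sensor_array(geom, nsub = config$sensors$nsub %||% 2L,
                                cap_axis = config$sensors$cap_axis %||% c(1, 0, 0),
                                cap_angle = config$sensors$cap_angle %||% pi)
  })

  bmmg <- run_stage("biomagnetics", {
    V <- matrix(0, nrow(full_mesh$nodes), length(vm$times))
    V[subM$node_map, ] <- vm$values
    out <- matrix(0, length(vm$times), nrow(sensors$positions))
    for (j in seq_along(vm$times)) {
      cur <- total_current(full_mesh, V[, j], phi$values[, j], cond, tf, lambda)
      B <- magnetic_field(cur, sensors$positions)
      out[j, ] <- mmg_projection(B, sensors)
    }
    out
  })

  metrics <- run_stage("metrics", {
    cf <- contracting_fraction(vm)
    probes <- lapply(config$probe_elevation, function(th) {
      rmid <- config$geometry$r_myo_outer - config$geometry$wall_thickness / 2
      c(rmid * sin(th), 0, rmid * cos(th))
    })
    wf <- lapply(probes, function(p) {
      tr <- probe_trace(vm, matrix(p, 1))
      names(tr)[2] <- "v_m"
      waveform_metrics(tr, resting = params$v_mr)
    })
    list(contracting = cf, waveforms = wf)
  })

  # ---- write artifacts ----
  run_stage("write", {
    write_vtk(full_mesh, file.path(out_dir, "mesh.vtk"),
              point_data = list(v_m_final = {
                V <- rep(0, nrow(full_mesh$nodes))
                V[subM$node_map] <- vm$values[, ncol(vm$values)]
                V
              }))
    write_sensor_csv(sensors, file.path(out_dir, "sensors.csv"))
    write.csv(metrics$contracting, file.path(out_dir, "contracting_fraction.csv"),
              row.names = FALSE)
    bdf <- as.data.frame(bmmg)
    names(bdf) <- paste0("s", sensors$ids)
    write.csv(cbind(t = vm$times, bdf), file.path(out_dir, "b_mmg.csv"),
              row.names = FALSE)
    ptr <- probe_trace(vm, do.call(rbind, lapply(config$probe_elevation,
      function(th) {
        rmid <- config$geometry$r_myo_outer - config$geometry$wall_thickness / 2
        c(rmid * sin(th), 0, rmid * cos(th))
      })))
    write.csv(ptr, file.path(out_dir, "probe_traces.csv"), row.names = FALSE)
    wsum <- do.call(rbind, lapply(metrics$waveforms, function(w)
      data.frame(ap = w$ap_detected, peak_mV = 1e3 * w$peak_vm,
                 plateau_mV = 1e3 * w$plateau_mean, duration_s = w$duration_s)))
    write.csv(wsum, file.path(out_dir, "waveform_metrics.csv"),
              row.names = FALSE)
    TRUE
  })

  cfg_file <- file.path(out_dir, "config.yaml")
  write_run_config(config, cfg_file)
  manifest <- list(
    package = "uterowave",
    version = as.character(utils::packageVersion("uterowave")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    wall_times_s = lapply(wall, function(x) round(x, 3)),
    n_nodes = nrow(full_mesh$nodes), n_elements = nrow(full_mesh$elems),
    dt = step1$dt, times = range(vm$times))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(geometry = geom, mesh = full_mesh, submesh = subM,
                 conductivity = cond, v_m = vm, phi = phi, b_mmg = bmmg,
                 sensors = sensors, metrics = metrics, manifest = manifest))
}
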