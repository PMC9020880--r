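# Case configuration and batch drivers: the Keller-Miksis validation run,
# the bubble-offset sweep (C = 0..7 um in a 10 um vessel) and the
# vessel-size sweep (r_i = 10..3 um at a fixed 1 um surface-wall gap).

#' Case configuration
#'
#' Bundles geometry, materials, drive and solver settings under a label;
#' serializable to YAML/JSON and reconstructable without loss.
#'
#' @param label case name
#' @param spec [geometry_spec()]
#' @param fluid [fluid_properties()]
#' @param solids list with `vessel` and `tissue` [solid_properties()]
#' @param drive [ultrasound_drive()]
#' @param config [solver_config()]
#' @param resolution mesh resolution preset name or parameter list
#' @return object of class `case_config`
#' @export
case_config <- function(label = "case",
                        spec = geometry_spec(),
                        fluid = fluid_properties(),
                        solids = default_solids(),
                        drive = ultrasound_drive(),
                        config = solver_config(),
                        resolution = "coarse") {
  structure(list(label = label, spec = spec, fluid = fluid, solids = solids,
                 drive = drive, config = config, resolution = resolution),
            class = "case_config")
}

#' @rdname case_config
#' @param x a `case_config`
#' @param path file path ending in `.yaml`, `.yml` or `.json`
#' @export
write_case_config <- function(x, path) {
  stopifnot(inherits(x, "case_config"))
  strip <- function(v) if (is.list(v)) lapply(unclass(v), strip) else v
  lst <- strip(unclass(x))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' @rdname case_config
#' @export
read_case_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  sp <- lst$spec
  fl <- lst$fluid
  dr <- lst$drive
  cf <- lst$config
  case_config(
    label = lst$label,
    spec = geometry_spec(sp$bubble_radius, sp$bubble_offset,
                         sp$vessel_inner_radius, sp$vessel_wall_thickness,
                         sp$tissue_outer_radius,
                         sp$absorbing_layer_thickness, sp$axial_half_length),
    fluid = fluid_properties(fl$density, fl$sound_speed, fl$viscosity,
                             fl$surface_tension, fl$ambient_pressure),
    solids = list(
      vessel = solid_properties(lst$solids$vessel$youngs_modulus,
                                lst$solids$vessel$poisson_ratio,
                                lst$solids$vessel$solid_density),
      tissue = solid_properties(lst$solids$tissue$youngs_modulus,
                                lst$solids$tissue$poisson_ratio,
                                lst$solids$tissue$solid_density)),
    drive = ultrasound_drive(dr$frequency, dr$amplitude, dr$phase,
                             if (is.null(dr$burst_duration)) Inf
                             else num(dr$burst_duration)),
    config = do.call(solver_config,
                     cf[setdiff(names(cf), character(0))]),
    resolution = if (is.character(lst$resolution)) lst$resolution
    else lapply(lst$resolution, function(v)
      if (is.numeric(v) && v == round(v)) as.integer(v) else v))
}

#' Run one configured case and summarize it
#'
#' @param case a [case_config()]
#' @param keep_run keep the full `fsi_result` in the output
#' @return list of class `case_result` with the stress summary, volume
#'   extrema, centroid/asymmetry traces and run metadata; `error` is set
#'   and the rest `NULL` when the solver fails
#' @export
run_case <- function(case, keep_run = FALSE) {
  stopifnot(inherits(case, "case_config"))
  res <- try(run_simulation(case$spec, case$fluid, case$solids, NULL,
                            case$drive, case$config, case$resolution),
             silent = TRUE)
  if (inherits(res, "try-error")) {
    return(structure(list(label = case$label, case = case,
                          error = attr(res, "condition")$message),
                     class = "case_result"))
  }
  traces <- sample_wall_traces(res)
  summ <- summarize_stresses(traces)
  A <- asymmetric_ratio(res)
  cen <- centroid_displacement(res)
  ms <- try(microstreaming_sides(res), silent = TRUE)
  mse <- try(microstreaming_mirror_error(res), silent = TRUE)
  structure(list(
    label = case$label, case = case, error = NULL,
    stress = summ,
    volume_extrema = c(max = max(res$volume), min = min(res$volume)),
    max_equiv_radius = max(res$equiv_radius),
    centroid = cen,
    asymmetry = A,
    max_asymmetry = max(A$A),
    microstreaming = if (inherits(ms, "try-error")) NULL else ms,
    microstreaming_mirror = if (inherits(mse, "try-error")) NULL else mse,
    gas_mass_drift = res$gas_mass_drift,
    div_residual_max = max(res$div_residual),
    run = if (keep_run) res else NULL),
    class = "case_result")
}

#' Validate the coupled solver against the radial dynamics equation
#'
#' Centered 2 um bubble in a 20 um vessel (bubble one tenth of the vessel
#' radius, minimal confinement) under the standard 130 kPa / 1 MHz drive;
#' the equivalent-radius trace of the coupled run is compared with the
#' free-bubble radial dynamics integration.
#'
#' @param t_end simulated duration [s]
#' @param resolution mesh resolution (name or parameter list)
#' @param dt time step [s]
#' @param drive [ultrasound_drive()]
#' @param normalization passed to [rms_deviation()]
#' @return list of class `validation_result`: `rms_percent`, the two traces
#'   and the run
#' @export
run_validation <- function(t_end = 2.5e-6, resolution = "coarse",
                           dt = 3e-9, drive = ultrasound_drive(),
                           normalization = "equilibrium_radius") {
  spec <- geometry_spec(bubble_radius = 2e-6, bubble_offset = 0,
                        vessel_inner_radius = 20e-6)
  cfg <- solver_config(t_end = t_end, dt_max = dt)
  res <- run_simulation(spec, drive = drive, config = cfg,
                        resolution = resolution)
  km <- solve_km(drive = drive, R0 = 2e-6, t_end = t_end,
                 n_samples = max(500L, length(res$times)))
  fem_trace <- radius_trace(res$times, res$equiv_radius,
                            c(0, diff(res$equiv_radius) / diff(res$times)),
                            params = list(R0 = 2e-6))
  rms <- rms_deviation(km, fem_trace, normalization = normalization,
                       R0 = 2e-6)
  structure(list(rms_percent = rms, km = km, fem = fem_trace, run = res),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> RMS deviation %.2f%% over %.2f us\n",
              x$rms_percent, max(x$fem$times) * 1e6))
  invisible(x)
}

# shared builder for the two sweeps
.sweep <- function(cases, keep_runs = FALSE) {
  out <- lapply(cases, run_case, keep_run = keep_runs)
  ok <- vapply(out, function(r) is.null(r$error), logical(1))
  structure(list(cases = out, complete = all(ok),
                 labels = vapply(out, `[[`, character(1), "label")),
            class = "sweep_result")
}

#' Bubble-offset sweep
#'
#' Eight cases with the 2 um bubble placed 0 to 7 um from the axis of a
#' 10 um vessel (surface-wall gaps 8 down to 1 um), identical materials and
#' drive throughout.  Failed cases are recorded and skipped, not fatal.
#'
#' @param offsets_um bubble offsets [um]
#' @param t_end,dt solver horizon and step [s]
#' @param resolution mesh resolution
#' @param drive [ultrasound_drive()]
#' @param keep_runs keep full runs (memory heavy)
#' @return object of class `sweep_result`
#' @export
run_offset_sweep <- function(offsets_um = 0:7, t_end = 2.5e-6, dt = 3e-9,
                             resolution = "coarse",
                             drive = ultrasound_drive(),
                             keep_runs = FALSE) {
  cases <- offset_sweep_cases(offsets_um, t_end, dt, resolution, drive)
  sw <- .sweep(cases, keep_runs)
  sw$axis <- list(name = "bubble_offset_um", values = offsets_um)
  sw
}

#' @rdname run_offset_sweep
#' @export
offset_sweep_cases <- function(offsets_um = 0:7, t_end = 2.5e-6, dt = 3e-9,
                               resolution = "coarse",
                               drive = ultrasound_drive()) {
  lapply(offsets_um, function(C) {
    case_config(label = sprintf("C_%gum", C),
                spec = geometry_spec(bubble_offset = C * 1e-6,
                                     vessel_inner_radius = 10e-6),
                drive = drive,
                config = solver_config(t_end = t_end, dt_max = dt),
                resolution = resolution)
  })
}

#' Vessel-size sweep
#'
#' Eight cases with vessel radius 10 down to 3 um and the bubble center
#' kept 3 um from the wall (C = r_i - 3 um); the last case is centered.
#'
#' @param radii_um vessel radii [um]
#' @inheritParams run_offset_sweep
#' @return object of class `sweep_result`
#' @export
run_vessel_size_sweep <- function(radii_um = 10:3, t_end = 2.5e-6,
                                  dt = 3e-9, resolution = "coarse",
                                  drive = ultrasound_drive(),
                                  keep_runs = FALSE) {
  cases <- vessel_size_sweep_cases(radii_um, t_end, dt, resolution, drive)
  sw <- .sweep(cases, keep_runs)
  sw$axis <- list(name = "vessel_radius_um", values = radii_um)
  sw
}

#' @rdname run_vessel_size_sweep
#' @export
vessel_size_sweep_cases <- function(radii_um = 10:3, t_end = 2.5e-6,
                                    dt = 3e-9, resolution = "coarse",
                                    drive = ultrasound_drive()) {
  lapply(radii_um, function(ri) {
    case_config(label = sprintf("ri_%gum", ri),
                spec = geometry_spec(bubble_offset = (ri - 3) * 1e-6,
                                     vessel_inner_radius = ri * 1e-6),
                drive = drive,
                config = solver_config(t_end = t_end, dt_max = dt),
                resolution = resolution)
  })
}

#' @export
print.sweep_result <- function(x, ...) {
  ok <- vapply(x$cases, function(r) is.null(r$error), logical(1))
  cat(sprintf("<sweep_result> %d/%d cases completed (%s)\n", sum(ok),
              length(ok), x$axis$name))
  invisible(x)
}

#' Tabulate per-angle maximum stresses across a sweep
#'
#' @param sweep a `sweep_result`
#' @param what `"max_sigma_cr"`, `"max_tau"`, `"min_sigma_cr"` or
#'   `"min_tau"`
#' @return data frame: one row per case, one column per azimuth
#' @export
sweep_stress_table <- function(sweep, what = "max_sigma_cr") {
  rows <- lapply(sweep$cases, function(r) {
    if (!is.null(r$error)) return(NULL)
    pa <- r$stress$per_angle
    stats::setNames(as.list(pa[[what]]), paste0("theta_", pa$theta_deg))
  })
  keep <- !vapply(rows, is.null, logical(1))
  df <- do.call(rbind, lapply(rows[keep], as.data.frame))
  df <- cbind(case = sweep$labels[keep],
              axis = sweep$axis$values[keep], df)
  names(df)[2] <- sweep$axis$name
  rownames(df) <- NULL
  df
}

#' Export sweep results as CSV + JSON report
#'
#' Writes the per-angle maximum hoop- and shear-stress tables, the volume
#' extrema, centroid and asymmetry traces, a machine-readable JSON summary,
#' a column-unit schema sidecar and a manifest with configuration hashes.
#'
#' @param results a `sweep_result` (possibly with zero completed cases)
#' @param outdir output directory, created if missing
#' @return character vector of written file paths, invisibly
#' @export
export_report <- function(results, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("export_report: cannot create output directory")
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  empty <- data.frame(case = character(0))
  hoop <- tryCatch(sweep_stress_table(results, "max_sigma_cr"),
                   error = function(e) empty)
  shear <- tryCatch(sweep_stress_table(results, "max_tau"),
                    error = function(e) empty)
  wr(if (is.null(hoop)) empty else hoop, "max_hoop_stress.csv")
  wr(if (is.null(shear)) empty else shear, "max_shear_stress.csv")
  vol <- do.call(rbind, lapply(results$cases, function(r) {
    if (!is.null(r$error)) return(NULL)
    data.frame(case = r$label, V_max_m3 = r$volume_extrema["max"],
               V_min_m3 = r$volume_extrema["min"],
               A_max = r$max_asymmetry)
  }))
  wr(if (is.null(vol)) data.frame(case = character(0), V_max_m3 = numeric(0),
                                  V_min_m3 = numeric(0), A_max = numeric(0))
     else vol, "volume_extrema.csv")
  cen <- do.call(rbind, lapply(results$cases, function(r) {
    if (!is.null(r$error)) return(NULL)
    data.frame(case = r$label, t_s = r$centroid$times, dy_m = r$centroid$d_y)
  }))
  wr(if (is.null(cen)) data.frame(case = character(0), t_s = numeric(0),
                                  dy_m = numeric(0)) else cen,
     "centroid_traces.csv")
  # machine summary + schema + manifest
  summ <- lapply(results$cases, function(r) {
    if (!is.null(r$error)) list(label = r$label, error = r$error)
    else list(label = r$label,
              max_sigma_cr_Pa = r$stress$global$max_sigma_cr,
              max_tau_Pa = r$stress$global$max_tau,
              V_max_m3 = unname(r$volume_extrema["max"]),
              V_min_m3 = unname(r$volume_extrema["min"]),
              A_max = r$max_asymmetry)
  })
  jp <- file.path(outdir, "summary.json")
  jsonlite::write_json(list(axis = results$axis, complete = results$complete,
                            cases = summ), jp, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, jp)
  schema <- list(
    max_hoop_stress.csv = "per azimuth station [deg]: maximum circumferential stress over the run [Pa]",
    max_shear_stress.csv = "per azimuth station [deg]: maximum wall shear stress over the run [Pa]",
    volume_extrema.csv = "V_max_m3/V_min_m3: bubble volume extrema [m^3]; A_max: peak asymmetric ratio [-]",
    centroid_traces.csv = "t_s: time [s]; dy_m: centroid displacement toward the near wall [m]")
  sp <- file.path(outdir, "schema.json")
  jsonlite::write_json(schema, sp, auto_unbox = TRUE)
  paths <- c(paths, sp)
  manifest <- lapply(results$cases, function(r) {
    cf <- tempfile(fileext = ".json")
    write_case_config(r$case, cf)
    h <- unname(tools::md5sum(cf))
    unlink(cf)
    list(label = r$label, config_md5 = h,
         completed = is.null(r$error))
  })
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE)
  paths <- c(paths, mp)
  invisible(paths)
}
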