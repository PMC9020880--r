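# Vessel-wall stress post-processing: thick-cylinder circumferential stress
# from the wall pressure and wall shear from the blood-side velocity
# gradient, sampled at the nine azimuthal stations in the bubble-center
# plane.

#' Thick-walled cylinder circumferential (hoop) stress
#'
#' Lame solution for a thick cylinder under internal gauge pressure `P_i`:
#' \deqn{\sigma_{cr}(r) = \frac{P_i r_i^2}{r_o^2 - r_i^2} +
#'   \frac{r_i^2 r_o^2}{r^2}\frac{P_i}{r_o^2 - r_i^2}.}
#' Linear in `P_i`; maximal at the inner surface `r = r_i`; tends to `P_i`
#' as the wall becomes infinitely thick.
#'
#' @param P_i inner-surface gauge pressure [Pa], may be a vector
#' @param r_i,r_o inner and outer wall radii [m]
#' @param r evaluation radius [m], must lie in `[r_i, r_o]`
#' @return hoop stress [Pa], same length as `P_i`
#' @export
#' @examples
#' lame_hoop_stress(100e3, 10e-6, 11e-6)   # ~1052 kPa at the inner surface
lame_hoop_stress <- function(P_i, r_i, r_o, r = r_i) {
  if (r_o <= r_i) stop("lame_hoop_stress: r_o must exceed r_i")
  if (r < r_i * (1 - 1e-12) || r > r_o * (1 + 1e-12))
    stop("lame_hoop_stress: r outside [r_i, r_o]")
  P_i * r_i^2 / (r_o^2 - r_i^2) + (r_i^2 * r_o^2 / r^2) * P_i / (r_o^2 - r_i^2)
}

#' Wall shear stress from the blood-side velocity gradient
#'
#' At the 0 and 180 degree stations (wall normal along y, vessel axis z)
#' this is literally \eqn{\tau_{yz} = \mu(\partial v/\partial z +
#' \partial w/\partial y)} with `v`, `w` the y- and z-velocities.  At other
#' azimuths the default generalization is the signed axial component of the
#' viscous traction, \eqn{\mu[(\nabla v + \nabla v^T)n]\cdot \hat z}, which
#' reduces exactly to \eqn{\tau_{yz}} when `n` is along y; the unsigned
#' tangential traction magnitude is available as an option.
#'
#' @param grad_v 3x3 velocity gradient `G[i,j] = dv_i/dx_j` on the blood
#'   side of the wall
#' @param normal unit outward wall normal at the evaluation point
#' @param mu dynamic viscosity [Pa s]
#' @param component `"axial"` (signed, default) or `"tangential_magnitude"`
#' @return shear stress [Pa]
#' @export
#' @examples
#' G <- matrix(0, 3, 3); G[2, 3] <- 2          # v_y = 2 z
#' wall_shear(G, c(0, 1, 0), mu = 0.005)       # mu * gamma = 0.01
wall_shear <- function(grad_v, normal, mu,
                       component = c("axial", "tangential_magnitude")) {
  component <- match.arg(component)
  stopifnot(is.matrix(grad_v), all(dim(grad_v) == c(3L, 3L)))
  tr <- mu * (grad_v + t(grad_v)) %*% normal
  tt <- tr - sum(tr * normal) * normal
  if (component == "axial") tt[3L] else sqrt(sum(tt^2))
}

#' Wall stress traces at the azimuthal stations
#'
#' Builds per-angle time series of wall gauge pressure, circumferential
#' stress (Lame formula at `r = r_i`) and wall shear from a simulation
#' result.  By default `P_i` is the bubble-scattered wall pressure (the
#' perturbation beyond the instantaneous ambient): the incident drive
#' pressurizes the vessel from inside and outside alike and therefore
#' carries no net hoop load; `gauge = "total"` adds the instantaneous
#' drive for the wall pressure relative to the static ambient.
#' Rarefaction phases give negative (compressive) hoop stress.
#'
#' @param run an `fsi_result`
#' @param eval_radius radius where the hoop stress is evaluated (default
#'   the inner surface, where it is maximal)
#' @param component shear convention passed to [wall_shear()]
#' @param gauge `"scattered"` (default) or `"total"`
#' @return list of data frames of class `wall_stress_trace`, one per
#'   azimuth, with columns `times`, `P_i`, `sigma_cr`, `tau`
#' @export
sample_wall_traces <- function(run, eval_radius = NULL,
                               component = "axial",
                               gauge = c("scattered", "total")) {
  gauge <- match.arg(gauge)
  stopifnot(inherits(run, "fsi_result"))
  spec <- run$system$mesh$spec
  r_i <- spec$vessel_inner_radius
  r_o <- r_i + spec$vessel_wall_thickness
  if (is.null(eval_radius)) eval_radius <- r_i
  mu <- run$system$fluid$viscosity
  st <- run$stations
  out <- vector("list", length(st$angles_deg))
  for (k in seq_along(st$angles_deg)) {
    P_i <- run$station_pressure[, k] +
      if (gauge == "total") run$drive_pressure else 0
    tau <- vapply(seq_along(run$times), function(s) {
      G <- matrix(run$station_gradv[s, k, ], 3L, 3L)
      wall_shear(G, st$normal[k, ], mu, component)
    }, numeric(1))
    df <- data.frame(times = run$times, P_i = P_i,
                     sigma_cr = lame_hoop_stress(P_i, r_i, r_o, eval_radius),
                     tau = tau)
    attr(df, "theta_deg") <- st$angles_deg[k]
    class(df) <- c("wall_stress_trace", "data.frame")
    out[[k]] <- df
  }
  names(out) <- paste0("theta_", st$angles_deg)
  out
}

#' Per-angle and global stress extrema
#'
#' @param traces result of [sample_wall_traces()]
#' @return object of class `stress_summary`: data frame `per_angle` with
#'   max/min hoop and shear stress and their times, plus `global` extrema
#' @export
summarize_stresses <- function(traces) {
  stopifnot(length(traces) > 0)
  rows <- lapply(traces, function(tr) {
    th <- attr(tr, "theta_deg")
    data.frame(theta_deg = th,
               max_sigma_cr = max(tr$sigma_cr),
               t_max_sigma = tr$times[which.max(tr$sigma_cr)],
               min_sigma_cr = min(tr$sigma_cr),
               t_min_sigma = tr$times[which.min(tr$sigma_cr)],
               max_tau = max(tr$tau),
               t_max_tau = tr$times[which.max(tr$tau)],
               min_tau = min(tr$tau),
               t_min_tau = tr$times[which.min(tr$tau)])
  })
  per_angle <- do.call(rbind, rows)
  rownames(per_angle) <- NULL
  gi <- which.max(per_angle$max_sigma_cr)
  gj <- which.max(per_angle$max_tau)
  out <- list(per_angle = per_angle,
              global = list(
                max_sigma_cr = per_angle$max_sigma_cr[gi],
                sigma_angle = per_angle$theta_deg[gi],
                sigma_time = per_angle$t_max_sigma[gi],
                max_tau = per_angle$max_tau[gj],
                tau_angle = per_angle$theta_deg[gj],
                tau_time = per_angle$t_max_tau[gj]))
  class(out) <- "stress_summary"
  out
}

#' @export
print.stress_summary <- function(x, ...) {
  g <- x$global
  cat(sprintf("<stress_summary> max hoop %.3g kPa @ %g deg (t = %.3g us); max shear %.3g kPa @ %g deg (t = %.3g us)\n",
              g$max_sigma_cr / 1e3, g$sigma_angle, g$sigma_time * 1e6,
              g$max_tau / 1e3, g$tau_angle, g$tau_time * 1e6))
  invisible(x)
}

#' Write stress traces to CSV
#'
#' Long format with columns `theta_deg`, `t_s`, `P_i_Pa`, `sigma_cr_Pa`,
#' `tau_Pa`.
#'
#' @param traces result of [sample_wall_traces()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_stress_traces <- function(traces, path) {
  long <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(theta_deg = attr(tr, "theta_deg"), t_s = tr$times,
               P_i_Pa = tr$P_i, sigma_cr_Pa = tr$sigma_cr, tau_Pa = tr$tau)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
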