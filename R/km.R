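#' Acoustic drive waveform
#'
#' Gauge acoustic pressure of the sinusoidal drive,
#' `-P_a * sin(2 pi f t + phase)` inside the burst window and 0 outside.
#' With the default phase the first half-cycle is rarefactional (negative),
#' so a free bubble grows before it is compressed.
#'
#' @param t time [s], scalar or vector, must be >= 0
#' @param drive an [ultrasound_drive()] object
#' @return acoustic gauge pressure [Pa], same length as `t`
#' @export
#' @examples
#' drive_pressure(0, ultrasound_drive())        # 0
#' drive_pressure(0.25e-6, ultrasound_drive())  # -130 kPa (quarter period)
drive_pressure <- function(t, drive = ultrasound_drive()) {
  stopifnot(inherits(drive, "ultrasound_drive"))
  if (any(t < 0)) stop("drive_pressure: t must be >= 0")
  p <- -drive$amplitude * sin(2 * pi * drive$frequency * t + drive$phase)
  p[t > drive$burst_duration] <- 0
  p
}

#' Keller-Miksis radial dynamics
#'
#' Right-hand side of the compressibility-corrected radial dynamics equation
#' for a free spherical bubble,
#' \deqn{(1 - \dot R/c) R \ddot R + \tfrac{3}{2}(1 - \dot R/(3c)) \dot R^2 =
#'   \frac{R}{\rho c} \frac{dP_b}{dt} +
#'   \frac{1}{\rho}(1 + \dot R/c) (P_b - P_\infty - p(t)),}
#' with the liquid pressure at the interface
#' \eqn{P_b = p_{g0} (R_0/R)^{3k} - 2\sigma/R - 4\mu\dot R/R}.
#' The radial acceleration appears implicitly inside \eqn{dP_b/dt} through
#' the viscous term; it is resolved algebraically (a single linear solve in
#' \eqn{\ddot R}) so the returned acceleration satisfies the equation exactly.
#'
#' @param t time [s]
#' @param R bubble radius [m], must be positive
#' @param Rdot interface velocity [m/s], must satisfy `|Rdot| < c`
#' @param fluid [fluid_properties()]
#' @param gas [gas_model()]
#' @param drive [ultrasound_drive()]
#' @param retarded_time if `TRUE` the drive is evaluated at `t + R/c`
#'   (the literal retarded argument); default `FALSE` since the retardation
#'   over micron scales is far below one acoustic period
#' @return list with elements `Rdot` and `Rddot` [m/s, m/s^2]
#' @export
km_derivatives <- function(t, R, Rdot,
                           fluid = fluid_properties(),
                           gas = gas_model(fluid = fluid),
                           drive = ultrasound_drive(),
                           retarded_time = FALSE) {
  if (R <= 0) stop("km_derivatives: model breakdown, R <= 0")
  c0 <- fluid$sound_speed
  if (abs(Rdot) >= c0) stop("km_derivatives: model breakdown, |Rdot| >= c")
  rho <- fluid$density
  mu <- fluid$viscosity
  sig <- fluid$surface_tension
  Pinf <- fluid$ambient_pressure
  k <- gas$polytropic_index
  R0 <- gas$equilibrium_radius
  pg0 <- gas$equilibrium_gas_pressure

  pg <- pg0 * (R0 / R)^(3 * k)
  Pb <- pg - 2 * sig / R - 4 * mu * Rdot / R
  t_eval <- if (retarded_time) t + R / c0 else t
  p_ac <- drive_pressure(t_eval, drive)

  # dPb/dt = A - 4 mu Rddot / R with the explicit part
  A <- -3 * k * pg * Rdot / R + 2 * sig * Rdot / R^2 + 4 * mu * Rdot^2 / R^2

  lhs_coef <- (1 - Rdot / c0) * R + 4 * mu / (rho * c0)
  rhs <- R / (rho * c0) * A +
    (1 + Rdot / c0) * (Pb - Pinf - p_ac) / rho -
    1.5 * (1 - Rdot / (3 * c0)) * Rdot^2
  Rddot <- rhs / lhs_coef
  if (!is.finite(Rddot)) stop("km_derivatives: non-finite acceleration")
  list(Rdot = Rdot, Rddot = Rddot)
}

#' Integrate the Keller-Miksis equation
#'
#' Adaptive stiff integration of the radial dynamics from rest
#' (`R(0) = R0`, `Rdot(0) = 0`) with dense output on a uniform sample grid.
#'
#' @inheritParams km_derivatives
#' @param R0 initial (equilibrium) radius [m]; also resets the gas model's
#'   equilibrium radius when it differs
#' @param t_end final time [s]
#' @param rtol,atol_R relative tolerance and absolute radius tolerance of the
#'   integrator (defaults 1e-9 and 1e-12 m)
#' @param n_samples number of output samples (uniform in time)
#' @param collapse_eps integration aborts with an error if `R` falls below
#'   `collapse_eps * R0` (model breakdown), reporting the failure time
#' @param method deSolve integrator name (default `"lsoda"`)
#' @return A `radius_trace`: data frame with columns `times`, `radii`,
#'   `velocities` and the parameter set stored as attributes.
#' @export
#' @examples
#' tr <- solve_km(t_end = 2e-6, n_samples = 200)
#' range(tr$radii) * 1e6   # radius excursion in um
solve_km <- function(fluid = fluid_properties(),
                     gas = gas_model(fluid = fluid),
                     drive = ultrasound_drive(),
                     R0 = gas$equilibrium_radius,
                     t_end = 5e-6,
                     rtol = 1e-9, atol_R = 1e-12,
                     n_samples = 2000,
                     collapse_eps = 1e-3,
                     retarded_time = FALSE,
                     method = "lsoda") {
  if (t_end <= 0) stop("solve_km: t_end must be positive")
  if (R0 != gas$equilibrium_radius) {
    gas <- gas_model(polytropic_index = gas$polytropic_index,
                     equilibrium_radius = R0, fluid = fluid,
                     gas_viscosity = gas$gas_viscosity,
                     temperature = gas$temperature,
                     universal_gas_constant = gas$universal_gas_constant,
                     molar_mass = gas$molar_mass, mode = gas$mode)
  }
  times <- seq(0, t_end, length.out = n_samples + 1L)
  rhs <- function(t, y, parms) {
    d <- km_derivatives(t, y[1L], y[2L], fluid, gas, drive, retarded_time)
    list(c(d$Rdot, d$Rddot))
  }
  rootfun <- function(t, y, parms) y[1L] - collapse_eps * R0
  sol <- deSolve::ode(y = c(R = R0, Rdot = 0), times = times, func = rhs,
                      parms = NULL, method = method,
                      rtol = rtol, atol = c(atol_R, 1e-6),
                      events = list(root = TRUE, terminalroot = 1L),
                      rootfun = rootfun)
  sol <- as.matrix(sol)
  if (nrow(sol) < length(times)) {
    stop(sprintf("solve_km: bubble collapsed below %g * R0 at t = %.4g s",
                 collapse_eps, sol[nrow(sol), 1L]))
  }
  radius_trace(times = sol[, 1L], radii = sol[, 2L], velocities = sol[, 3L],
               params = list(fluid = fluid, gas = gas, drive = drive,
                             R0 = R0, rtol = rtol, atol_R = atol_R,
                             method = method))
}

#' Radius trace container
#'
#' @param times strictly increasing sample times [s]
#' @param radii bubble radii [m], all positive
#' @param velocities interface velocities [m/s]
#' @param params optional parameter list stored as an attribute
#' @return data frame of class `radius_trace`
#' @export
radius_trace <- function(times, radii, velocities, params = NULL) {
  n <- length(times)
  if (length(radii) != n || length(velocities) != n)
    stop("radius_trace: times, radii, velocities must have equal length")
  if (n > 1L && any(diff(times) <= 0))
    stop("radius_trace: times must be strictly increasing")
  if (any(radii <= 0)) stop("radius_trace: radii must be positive")
  out <- data.frame(times = as.numeric(times), radii = as.numeric(radii),
                    velocities = as.numeric(velocities))
  attr(out, "params") <- params
  class(out) <- c("radius_trace", "data.frame")
  out
}

#' @export
print.radius_trace <- function(x, ...) {
  cat(sprintf("<radius_trace> %d samples over [%g, %g] us\n", nrow(x),
              min(x$times) * 1e6, max(x$times) * 1e6))
  cat(sprintf("  R in [%.4g, %.4g] um\n", min(x$radii) * 1e6,
              max(x$radii) * 1e6))
  invisible(x)
}

#' Residual of the radial dynamics equation along a trace
#'
#' Re-substitutes a trace into the equation of motion: at every interior
#' sample the acceleration is estimated by central differences of the stored
#' velocities and compared with the model acceleration.  Used to verify that
#' an integration actually satisfies the dynamics.
#'
#' @param trace a `radius_trace`
#' @inheritParams km_derivatives
#' @return maximum relative residual (dimensionless)
#' @export
km_residual <- function(trace, fluid = fluid_properties(),
                        gas = gas_model(fluid = fluid),
                        drive = ultrasound_drive()) {
  t <- trace$times; R <- trace$radii; Rd <- trace$velocities
  n <- length(t)
  idx <- 2:(n - 1L)
  acc_fd <- (Rd[idx + 1L] - Rd[idx - 1L]) / (t[idx + 1L] - t[idx - 1L])
  acc_model <- vapply(idx, function(i) {
    km_derivatives(t[i], R[i], Rd[i], fluid, gas, drive)$Rddot
  }, numeric(1))
  scale <- max(abs(acc_model)) + .Machine$double.eps
  max(abs(acc_fd - acc_model)) / scale
}

#' Linearized resonance frequency of a free bubble
#'
#' Natural frequency of small-amplitude radial oscillation,
#' \deqn{\omega_0^2 = \frac{3 k (P_\infty + 2\sigma/R_0) - 2\sigma/R_0}
#'   {\rho R_0^2},}
#' returned as `omega_0 / (2 pi)` in Hz.  With `sigma = 0` and `k = 1` this
#' reduces to the Minnaert frequency.
#'
#' @inheritParams km_derivatives
#' @param R0 equilibrium radius [m]
#' @return resonance frequency [Hz]
#' @export
linear_resonance_frequency <- function(fluid = fluid_properties(),
                                       gas = gas_model(fluid = fluid),
                                       R0 = gas$equilibrium_radius) {
  if (R0 <= 0) stop("linear_resonance_frequency: R0 must be positive")
  sig <- fluid$surface_tension
  stiff <- 3 * gas$polytropic_index *
    (fluid$ambient_pressure + 2 * sig / R0) - 2 * sig / R0
  if (stiff <= 0)
    stop("linear_resonance_frequency: non-positive effective stiffness")
  sqrt(stiff / (fluid$density * R0^2)) / (2 * pi)
}

#' Root-mean-square deviation between two radius traces
#'
#' Both traces are linearly interpolated onto the coarser of the two sample
#' grids restricted to the overlapping time range; the deviation is
#' \eqn{\sqrt{\mathrm{mean}((R_a - R_b)^2)}} divided by a normalization and
#' expressed in percent.
#'
#' @param trace_a reference `radius_trace`
#' @param trace_b comparison `radius_trace`
#' @param normalization `"equilibrium_radius"` divides by `R0` (taken from
#'   `trace_a`'s parameters unless given); `"reference_trace"` divides by the
#'   RMS of the reference radii over the overlap
#' @param R0 equilibrium radius [m] for the `"equilibrium_radius"` choice
#' @return deviation in percent
#' @export
rms_deviation <- function(trace_a, trace_b,
                          normalization = c("equilibrium_radius",
                                            "reference_trace"),
                          R0 = NULL) {
  normalization <- match.arg(normalization)
  t0 <- max(min(trace_a$times), min(trace_b$times))
  t1 <- min(max(trace_a$times), max(trace_b$times))
  if (t0 >= t1) stop("rms_deviation: traces have disjoint time ranges")
  # coarser grid = larger median spacing
  da <- stats::median(diff(trace_a$times))
  db <- stats::median(diff(trace_b$times))
  grid <- if (da >= db) trace_a$times else trace_b$times
  grid <- grid[grid >= t0 & grid <= t1]
  Ra <- stats::approx(trace_a$times, trace_a$radii, xout = grid)$y
  Rb <- stats::approx(trace_b$times, trace_b$radii, xout = grid)$y
  rms <- sqrt(mean((Ra - Rb)^2))
  denom <- if (normalization == "equilibrium_radius") {
    if (is.null(R0)) {
      p <- attr(trace_a, "params")
      if (is.null(p$R0)) stop("rms_deviation: R0 not given and not stored in trace_a")
      p$R0
    } else R0
  } else {
    sqrt(mean(Ra^2))
  }
  100 * rms / denom
}

#' Read/write radius traces
#'
#' CSV columns are `t_s`, `R_m`, `Rdot_m_s`; all scalar parameters are stored
#' in a JSON sidecar (same path with extension `.json`) when available.
#'
#' @param trace a `radius_trace`
#' @param path CSV file path
#' @return `write_radius_trace` returns `path` invisibly; `read_radius_trace`
#'   returns a `radius_trace`.
#' @export
write_radius_trace <- function(trace, path) {
  df <- data.frame(t_s = trace$times, R_m = trace$radii,
                   Rdot_m_s = trace$velocities)
  utils::write.csv(df, path, row.names = FALSE)
  p <- attr(trace, "params")
  if (!is.null(p)) {
    strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
    jsonlite::write_json(strip(p), sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_radius_trace
#' @export
read_radius_trace <- function(path) {
  df <- utils::read.csv(path)
  radius_trace(df$t_s, df$R_m, df$Rdot_m_s)
}
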