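#' Physical property containers
#'
#' Constructors for the material and drive parameter sets used throughout the
#' package.  Defaults correspond to an air microbubble in blood inside a
#' microvessel: blood density 1055 kg/m^3, sound speed 1500 m/s, viscosity
#' 0.005 Pa s, surface tension 0.072 N/m and ambient pressure 104.6 kPa.
#'
#' @param density fluid density [kg/m^3]
#' @param sound_speed speed of sound in the fluid [m/s]
#' @param viscosity dynamic viscosity [Pa s]
#' @param surface_tension gas-liquid surface tension [N/m]
#' @param ambient_pressure static far-field pressure [Pa]
#' @return An object of class `fluid_properties`.
#' @export
#' @examples
#' fluid_properties()           # blood defaults
#' fluid_properties(density = 1000, viscosity = 1e-3)  # water-like
fluid_properties <- function(density = 1055,
                             sound_speed = 1500,
                             viscosity = 0.005,
                             surface_tension = 0.072,
                             ambient_pressure = 104600) {
  x <- list(density = density, sound_speed = sound_speed,
            viscosity = viscosity, surface_tension = surface_tension,
            ambient_pressure = ambient_pressure)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("fluid_properties: '", nm, "' must be a single positive number")
  }
  structure(x, class = "fluid_properties")
}

#' @param polytropic_index polytropic exponent k of the gas law (1 = isothermal)
#' @param equilibrium_radius bubble equilibrium radius R0 [m]
#' @param fluid `fluid_properties` used to set the Laplace-balanced
#'   equilibrium gas pressure `p_g0 = P_inf + 2 sigma / R0`
#' @param gas_viscosity gas dynamic viscosity [Pa s]
#' @param temperature absolute temperature [K]
#' @param universal_gas_constant J/(mol K)
#' @param molar_mass gas molar mass [kg/mol] (air), used by the lumped
#'   ideal-gas tier to convert pressure to density
#' @param mode `"uniform_polytropic"` (default) or `"ideal_gas_compressible"`
#' @rdname fluid_properties
#' @export
gas_model <- function(polytropic_index = 1,
                      equilibrium_radius = 2e-6,
                      fluid = fluid_properties(),
                      gas_viscosity = 1.814e-5,
                      temperature = 293,
                      universal_gas_constant = 8.3145,
                      molar_mass = 0.0289647,
                      mode = c("uniform_polytropic", "ideal_gas_compressible")) {
  mode <- match.arg(mode)
  if (polytropic_index < 1) stop("gas_model: polytropic_index must be >= 1")
  if (equilibrium_radius <= 0) stop("gas_model: equilibrium_radius must be positive")
  p_g0 <- fluid$ambient_pressure + 2 * fluid$surface_tension / equilibrium_radius
  structure(list(polytropic_index = polytropic_index,
                 equilibrium_radius = equilibrium_radius,
                 equilibrium_gas_pressure = p_g0,
                 gas_viscosity = gas_viscosity,
                 temperature = temperature,
                 universal_gas_constant = universal_gas_constant,
                 molar_mass = molar_mass,
                 mode = mode),
            class = "gas_model")
}

#' @param frequency drive frequency [Hz]
#' @param amplitude peak acoustic pressure [Pa]
#' @param phase phase offset [rad]; the default 0 makes the first half-cycle
#'   rarefactional so the bubble grows first
#' @param burst_duration burst length [s]; drive is zero outside the burst
#' @rdname fluid_properties
#' @export
ultrasound_drive <- function(frequency = 1e6,
                             amplitude = 130e3,
                             phase = 0,
                             burst_duration = Inf) {
  if (frequency <= 0) stop("ultrasound_drive: frequency must be positive")
  if (amplitude < 0) stop("ultrasound_drive: amplitude must be non-negative")
  if (burst_duration <= 0) stop("ultrasound_drive: burst_duration must be positive")
  structure(list(frequency = frequency, amplitude = amplitude,
                 phase = phase, burst_duration = burst_duration),
            class = "ultrasound_drive")
}

#' @param youngs_modulus Young's modulus E [Pa]
#' @param poisson_ratio Poisson ratio (must be < 0.5)
#' @param solid_density solid density [kg/m^3]
#' @rdname fluid_properties
#' @export
solid_properties <- function(youngs_modulus = 1.5e6,
                             poisson_ratio = 0.49,
                             solid_density = 1070) {
  if (youngs_modulus <= 0) stop("solid_properties: youngs_modulus must be positive")
  if (poisson_ratio >= 0.5 || poisson_ratio <= -1)
    stop("solid_properties: poisson_ratio must lie in (-1, 0.5)")
  if (solid_density <= 0) stop("solid_properties: solid_density must be positive")
  structure(list(youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio,
                 solid_density = solid_density),
            class = "solid_properties")
}

#' Default vessel-wall and perivascular-tissue elastic properties
#'
#' Vessel: E = 1.5 MPa, rho = 1070 kg/m^3.  Tissue: E = 0.5 MPa,
#' rho = 1055 kg/m^3.  Both with Poisson ratio 0.49.
#' @return A list with elements `vessel` and `tissue`.
#' @export
default_solids <- function() {
  list(vessel = solid_properties(1.5e6, 0.49, 1070),
       tissue = solid_properties(0.5e6, 0.49, 1055))
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat("<fluid_properties>",
      sprintf("rho = %g kg/m^3, c = %g m/s, mu = %g Pa s", x$density,
              x$sound_speed, x$viscosity),
      sprintf("sigma = %g N/m, P_inf = %g Pa", x$surface_tension,
              x$ambient_pressure), sep = "\n")
  invisible(x)
}

#' @export
print.gas_model <- function(x, ...) {
  cat("<gas_model>",
      sprintf("mode = %s, k = %g, R0 = %g um", x$mode, x$polytropic_index,
              x$equilibrium_radius * 1e6),
      sprintf("p_g0 = %g Pa (Laplace-balanced), T = %g K",
              x$equilibrium_gas_pressure, x$temperature), sep = "\n")
  invisible(x)
}

#' @export
print.ultrasound_drive <- function(x, ...) {
  cat("<ultrasound_drive>",
      sprintf("f = %g MHz, P_a = %g kPa, phase = %g rad, burst = %g s",
              x$frequency / 1e6, x$amplitude / 1e3, x$phase,
              x$burst_duration), sep = "\n")
  invisible(x)
}
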