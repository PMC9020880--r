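#' Parametric bubble-blood-vessel-tissue geometry
#'
#' Half-symmetry geometry of a spherical gas microbubble inside a cylindrical
#' elastic vessel embedded in tissue with an outer absorbing layer.
#' Coordinate convention: vessel axis = z, symmetry plane = x = 0 (the
#' modelled half is x >= 0), bubble center at (0, C, 0).  The azimuthal angle
#' on the vessel wall is measured from +y (the bubble-offset direction), so
#' 0 deg is the wall point nearest the bubble and 180 deg the far side.
#'
#' @param bubble_radius equilibrium bubble radius R0 [m]
#' @param bubble_offset distance C of the bubble center from the vessel axis
#'   along +y [m]
#' @param vessel_inner_radius lumen radius r_i [m]
#' @param vessel_wall_thickness wall thickness h [m] (so r_o = r_i + h)
#' @param tissue_outer_radius outer radius of the tissue annulus [m];
#'   default 3 * r_o
#' @param absorbing_layer_thickness thickness of the outer absorbing
#'   (sponge) layer [m]; default r_o
#' @param axial_half_length half-length L of the modelled vessel segment [m];
#'   default max(3 * r_i, 5 * R0)
#' @return object of class `geometry_spec`
#' @export
#' @examples
#' geometry_spec()                          # centered 2 um bubble, 10 um vessel
#' geometry_spec(bubble_offset = 7e-6)      # closest-offset case (1 um gap)
geometry_spec <- function(bubble_radius = 2e-6,
                          bubble_offset = 0,
                          vessel_inner_radius = 10e-6,
                          vessel_wall_thickness = 1e-6,
                          tissue_outer_radius = NULL,
                          absorbing_layer_thickness = NULL,
                          axial_half_length = NULL) {
  r_o <- vessel_inner_radius + vessel_wall_thickness
  if (is.null(tissue_outer_radius)) tissue_outer_radius <- 3 * r_o
  if (is.null(absorbing_layer_thickness)) absorbing_layer_thickness <- r_o
  if (is.null(axial_half_length))
    axial_half_length <- max(3 * vessel_inner_radius, 5 * bubble_radius)
  x <- list(bubble_radius = bubble_radius,
            bubble_offset = bubble_offset,
            vessel_inner_radius = vessel_inner_radius,
            vessel_wall_thickness = vessel_wall_thickness,
            tissue_outer_radius = tissue_outer_radius,
            absorbing_layer_thickness = absorbing_layer_thickness,
            axial_half_length = axial_half_length)
  num <- vapply(x, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                logical(1))
  if (!all(num)) stop("geometry_spec: all fields must be finite scalars")
  if (bubble_radius <= 0 || vessel_inner_radius <= 0 ||
      vessel_wall_thickness <= 0 || absorbing_layer_thickness <= 0 ||
      axial_half_length <= 0)
    stop("geometry_spec: dimensions must be positive")
  if (bubble_offset < 0) stop("geometry_spec: bubble_offset must be >= 0")
  if (tissue_outer_radius <= r_o)
    stop("geometry_spec: tissue_outer_radius must exceed the vessel outer radius")
  structure(x, class = "geometry_spec")
}

#' Validate a geometry and derive its secondary quantities
#'
#' Checks the nesting constraints (in particular that the bubble lies
#' strictly inside the lumen) and returns the validated geometry with derived
#' quantities: outer wall radius `r_o`, bubble-surface to wall gap
#' `gap = r_i - C - R0`, and the analytic region volumes of the half model.
#'
#' @param spec a [geometry_spec()]
#' @return object of class `geometry`, a list with the spec, `r_o`, `gap`,
#'   and `volumes` (half-model analytic volumes in m^3 per region)
#' @export
#' @examples
#' g <- build_geometry(geometry_spec())
#' g$gap * 1e6   # 8 um for the centered default
build_geometry <- function(spec = geometry_spec()) {
  stopifnot(inherits(spec, "geometry_spec"))
  R0 <- spec$bubble_radius; C <- spec$bubble_offset
  r_i <- spec$vessel_inner_radius
  r_o <- r_i + spec$vessel_wall_thickness
  L <- spec$axial_half_length
  if (C + R0 >= r_i)
    stop("build_geometry: bubble-wall contact (C + R0 >= r_i)")
  if (R0 >= L) stop("build_geometry: bubble does not fit axially")
  r_t <- spec$tissue_outer_radius
  r_p <- r_t + spec$absorbing_layer_thickness
  vol_gas <- 2 / 3 * pi * R0^3                       # half ball
  vol_cyl <- function(r) pi * r^2 * (2 * L) / 2      # half cylinder/annulus
  volumes <- c(gas = vol_gas,
               blood = vol_cyl(r_i) - vol_gas,
               vessel = vol_cyl(r_o) - vol_cyl(r_i),
               tissue = vol_cyl(r_t) - vol_cyl(r_o),
               pml = vol_cyl(r_p) - vol_cyl(r_t))
  structure(list(spec = spec, r_o = r_o, r_pml_outer = r_p,
                 gap = r_i - C - R0, volumes = volumes),
            class = "geometry")
}

#' @export
print.geometry_spec <- function(x, ...) {
  cat("<geometry_spec>",
      sprintf("R0 = %g um at offset C = %g um", x$bubble_radius * 1e6,
              x$bubble_offset * 1e6),
      sprintf("vessel r_i = %g um, wall h = %g um, half-length L = %g um",
              x$vessel_inner_radius * 1e6, x$vessel_wall_thickness * 1e6,
              x$axial_half_length * 1e6),
      sep = "\n")
  invisible(x)
}

#' @export
print.geometry <- function(x, ...) {
  print(x$spec)
  cat(sprintf("gap (bubble surface to wall) = %g um\n", x$gap * 1e6))
  invisible(x)
}
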