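# Pressure and flow laws of centrifugal perfusion.
#
# A rotating liquid column between radii r1 < r2 develops the centrifugal
# pressure difference dp_c = 1/2 rho omega^2 (r2^2 - r1^2); the out-of-plane
# fluid level H adds the constant hydrostatic term dp_h = rho g H. The
# resulting flow through a shallow rectangular channel follows the
# Hagen-Poiseuille law with the first-order aspect-ratio correction
# (1 - 0.630 h/w). The exit port acts as a capillary burst valve with
# maximum burst pressure p_v = -4 sigma cos(theta_max) / d.

#' Centrifugal pressure difference along a rotating liquid column
#'
#' dp_c = 1/2 rho omega^2 (r2^2 - r1^2), the pressure generated between the
#' inner radius r1 and the outer radius r2 of the liquid volume. Scales with
#' omega^2 and vanishes at rest or for a zero-length column.
#'
#' @param fluid A [fluid_properties()] object.
#' @param state A [spin_state()] or rotation speed in rpm.
#' @param r1,r2 Inner and outer radii of the liquid column in m; requires
#'   0 <= r1 <= r2.
#' @return Pressure difference in Pa.
#' @examples
#' centrifugal_pressure(water_properties(37), 100, r1 = 10e-3, r2 = 45e-3)
#' @export
centrifugal_pressure <- function(fluid, state, r1, r2) {
  stopifnot(inherits(fluid, "fluid_properties"), is.numeric(r1), is.numeric(r2))
  if (any(r1 < 0)) abort("`r1` must be >= 0.")
  if (any(r2 < r1)) abort("`r2` must be >= `r1` (outer radius of the liquid column).")
  0.5 * fluid$density * as_omega(state)^2 * (r2^2 - r1^2)
}

#' Hydrostatic pressure of the fluid head
#'
#' dp_h = rho g0 H for a fluid level H above the inlet, perpendicular to the
#' disc plane. During rotation the inner compartment stays full to the brim
#' while the effluent is pushed past the outlet port, so this term is
#' constant while the disc spins.
#'
#' @param fluid A [fluid_properties()] object.
#' @param head Fluid level H in m, >= 0 (vectorized).
#' @return Pressure in Pa.
#' @examples
#' hydrostatic_pressure(water_properties(37), 8e-3) # ~78 Pa
#' @export
hydrostatic_pressure <- function(fluid, head) {
  stopifnot(inherits(fluid, "fluid_properties"), is.numeric(head))
  if (any(head < 0)) abort("`head` must be >= 0.")
  fluid$density * G0 * head
}

#' Maximum burst pressure of a circular capillary valve
#'
#' p_v = -4 sigma cos(theta_max) / d for liquid pinned inside a circular
#' capillary of inner diameter d, where theta_max is the largest contact
#' angle the meniscus can build before spreading into the diverging section.
#' The most conservative assumption theta_max = 180 deg gives p_v = 4
#' sigma / d; at 90 deg the valve holds nothing.
#'
#' @param fluid A [fluid_properties()] object.
#' @param port_diameter Inner diameter d of the capillary in m, > 0.
#' @param theta_max_deg Maximum contact angle in degrees, in `[0, 180]`
#'   (default 180).
#' @return Burst pressure in Pa (negative below 90 deg, where the wetting
#'   meniscus pulls liquid forward instead of pinning it).
#' @examples
#' burst_pressure(water_properties(37), 2e-3) # 140 Pa for a 2 mm port
#' @export
burst_pressure <- function(fluid, port_diameter, theta_max_deg = 180) {
  stopifnot(inherits(fluid, "fluid_properties"), is.numeric(port_diameter),
            is.numeric(theta_max_deg))
  if (any(port_diameter <= 0)) abort("`port_diameter` must be > 0.")
  if (any(theta_max_deg < 0 | theta_max_deg > 180)) {
    abort("`theta_max_deg` must lie in [0, 180] degrees.")
  }
  -4 * fluid$surface_tension * cospi(theta_max_deg / 180) / port_diameter
}

#' Hydraulic conductance of the rectangular media channel
#'
#' The proportionality Q = C * dp of the shallow-rectangular-channel flow
#' law: C = h^3 w / (12 eta L) * (1 - 0.630 h/w). Valid for h much smaller
#' than w; see [validate_geometry()] for the h/w > 0.5 warning.
#'
#' @param geom A [disc_geometry()] object.
#' @param fluid A [fluid_properties()] object.
#' @return Conductance in (m^3/s)/Pa.
#' @export
channel_conductance <- function(geom, fluid) {
  stopifnot(inherits(geom, "disc_geometry"), inherits(fluid, "fluid_properties"))
  v <- validate_geometry(geom)
  if (any(v$level == "error")) {
    abort(paste0("Invalid geometry:\n", paste0("- ", v$message[v$level == "error"],
                                               collapse = "\n")))
  }
  h <- geom$channel_height; w <- geom$channel_width; L <- geom$channel_length
  h^3 * w / (12 * fluid$viscosity * L) * (1 - 0.630 * h / w)
}

#' Volumetric flow through the rectangular media channel
#'
#' Q = h^3 w dp / (12 eta L) * (1 - 0.630 h/w), linear in the driving
#' pressure. A negative `dp` returns a negative (reversed) flow.
#'
#' @param geom A [disc_geometry()] object.
#' @param fluid A [fluid_properties()] object.
#' @param dp Driving pressure difference in Pa (vectorized).
#' @param units Output units: `"m3_s"` (SI, default) or `"ul_h"`.
#' @return Volumetric flow in the requested units.
#' @examples
#' geom <- organ_disc_geometry()
#' channel_flow(geom, water_properties(37), dp = 100, units = "ul_h") # ~247 ul/h
#' @export
channel_flow <- function(geom, fluid, dp, units = c("m3_s", "ul_h")) {
  units <- match.arg(units)
  stopifnot(is.numeric(dp))
  q <- channel_conductance(geom, fluid) * dp
  if (units == "ul_h") m3_s_to_ul_h(q) else q
}

#' Pressure budget of the perfusion at a given speed
#'
#' Collects the terms that drive (and oppose) flow at one rotation speed:
#' the centrifugal pressure over the pumping column, the constant
#' hydrostatic head, their sum as the total driving pressure, and the
#' capillary burst pressure of the exit port at the stated maximum contact
#' angle. Pinning is *not* subtracted here — whether and how it reduces the
#' budget is the business of the flow-model variants (see [flow_model()]).
#'
#' @param geom A [disc_geometry()] object.
#' @param fluid A [fluid_properties()] object.
#' @param state A [spin_state()] or rotation speed in rpm.
#' @param theta_max_deg Maximum contact angle for the burst-pressure term.
#' @return A tibble with one row: `speed_rpm`, `dp_centrifugal_pa`,
#'   `dp_hydrostatic_pa`, `dp_total_driving_pa`, `p_burst_pa`.
#' @examples
#' pressure_budget(organ_disc_geometry(), water_properties(37), 100)
#' @export
pressure_budget <- function(geom, fluid, state, theta_max_deg = 180) {
  stopifnot(inherits(geom, "disc_geometry"))
  state <- if (inherits(state, "spin_state")) state else spin_state(state)
  dp_c <- centrifugal_pressure(fluid, state, geom$r_inner, geom$r_outer)
  dp_h <- hydrostatic_pressure(fluid, geom$head_height)
  tibble(
    speed_rpm = state$speed_rpm,
    dp_centrifugal_pa = dp_c,
    dp_hydrostatic_pa = dp_h,
    dp_total_driving_pa = dp_c + dp_h,
    p_burst_pa = burst_pressure(fluid, geom$port_diameter, theta_max_deg)
  )
}
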