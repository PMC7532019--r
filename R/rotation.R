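#' Spin state of the disc
#'
#' A rotation speed with its derived angular velocity and an optional
#' duration. Angular velocity is always omega = 2*pi*speed/60 exactly.
#'
#' @param speed_rpm Rotation speed in rpm, >= 0.
#' @param duration_s Optional duration in seconds, > 0 when given.
#' @return An object of class `spin_state` with fields `speed_rpm`,
#'   `omega` (rad/s) and `duration_s`.
#' @examples
#' spin_state(100) # perfusion speed
#' spin_state(1000, duration_s = 300) # 5 min loading spin
#' @export
spin_state <- function(speed_rpm, duration_s = NA_real_) {
  stopifnot(is.numeric(speed_rpm), length(speed_rpm) == 1, speed_rpm >= 0)
  if (!is.na(duration_s)) stopifnot(duration_s > 0)
  structure(
    list(speed_rpm = speed_rpm, omega = rpm_to_rad_s(speed_rpm),
         duration_s = duration_s),
    class = "spin_state"
  )
}

#' @export
print.spin_state <- function(x, ...) {
  cat(sprintf("<spin_state> %g rpm (omega = %.4g rad/s)", x$speed_rpm, x$omega))
  if (!is.na(x$duration_s)) cat(sprintf(", %g s", x$duration_s))
  cat("\n")
  invisible(x)
}

as_omega <- function(state) {
  if (inherits(state, "spin_state")) state$omega else rpm_to_rad_s(state)
}

#' Centrifugal acceleration and relative centrifugal force
#'
#' `centrifugal_acceleration()` returns omega^2 * r in m/s^2 at a radial
#' position; `rcf()` expresses it in multiples of standard gravity
#' ([G0]). Both accept a [spin_state()] or a plain speed in rpm and are
#' vectorized over `radius`.
#'
#' @param state A [spin_state()] or a numeric rotation speed in rpm.
#' @param radius Radial position in m, >= 0.
#' @return Acceleration in m/s^2 (`centrifugal_acceleration`) or
#'   dimensionless multiples of g (`rcf`).
#' @examples
#' rcf(1000, 41.5e-3) # ~46.4 g at the tissue chambers
#' rcf(100, 41.5e-3)  # ~0.46 g during perfusion
#' @export
centrifugal_acceleration <- function(state, radius) {
  stopifnot(is.numeric(radius))
  if (any(radius < 0)) abort("`radius` must be >= 0.")
  as_omega(state)^2 * radius
}

#' @rdname centrifugal_acceleration
#' @export
rcf <- function(state, radius) {
  centrifugal_acceleration(state, radius) / G0
}

#' Effective gravity sensed by cells on a rotating disc
#'
#' Cells on a slowly rotating disc experience the in-plane centrifugal
#' acceleration and standard gravity (perpendicular to the disc plane)
#' simultaneously; the magnitude of their vector sum, in multiples of g, is
#' sqrt(1 + rcf^2). It is always >= 1 g and approaches 1 g as the rotation
#' stops, which is why perfusion speeds are chosen so the in-plane RCF stays
#' below 1 g.
#'
#' @param rcf_inplane In-plane relative centrifugal force in multiples of
#'   g; must be >= 0 (vectorized).
#' @return Effective gravity in multiples of g.
#' @examples
#' effective_gravity(0.46) # ~1.1 g at 100 rpm
#' effective_gravity(0)    # stationary disc: exactly 1 g
#' @export
effective_gravity <- function(rcf_inplane) {
  stopifnot(is.numeric(rcf_inplane))
  if (any(rcf_inplane < 0)) abort("`rcf_inplane` must be >= 0.")
  sqrt(1 + rcf_inplane^2)
}

#' Rotation speed required for a target relative centrifugal force
#'
#' Inverts rcf = omega^2 r / g0 for the speed: omega = sqrt(rcf * g0 / r).
#' Round-trips with [rcf()] to better than 1e-9 relative.
#'
#' @param target_rcf Target RCF in multiples of g, >= 0 (vectorized).
#' @param radius Radial position in m, > 0 (unless `target_rcf` is 0).
#' @return Rotation speed in rpm.
#' @examples
#' speed_for_rcf(46.4, 41.5e-3) # ~1000 rpm
#' @export
speed_for_rcf <- function(target_rcf, radius) {
  stopifnot(is.numeric(target_rcf), is.numeric(radius))
  if (any(target_rcf < 0)) abort("`target_rcf` must be >= 0.")
  if (any(radius <= 0 & target_rcf > 0)) {
    abort("Unreachable target: a positive RCF requires a positive radius.")
  }
  omega <- sqrt(target_rcf * G0 / ifelse(target_rcf == 0, 1, radius))
  rad_s_to_rpm(ifelse(target_rcf == 0, 0, omega))
}

#' Rotor radius presets
#'
#' Two named radial positions used in the workflows around the disc: the
#' tissue-chamber radius of the disc itself (41.5 mm, back-derived from the
#' loading anchor 1000 rpm = 46.4 g) and the rotor radius of a benchtop
#' centrifuge used for cell washing (193.2 mm, back-derived from its printed
#' 1000 rpm = 216 g anchor; kept separate from the disc geometry so the two
#' are never mixed).
#'
#' @return A tibble with columns `preset`, `radius_m`, `provenance` and
#'   `anchor`.
#' @examples
#' rotor_presets()
#' @export
rotor_presets <- function() {
  tibble(
    preset = c("disc_chamber", "benchtop_centrifuge"),
    radius_m = c(41.5e-3, 0.19316),
    provenance = c("derived", "derived"),
    anchor = c("1000 rpm = 46.4 g", "1000 rpm = 216 g")
  )
}

#' Tabulate RCF and effective gravity over a set of speeds
#'
#' Convenience table for protocol design: for each speed, the in-plane RCF
#' at the given radius, its display formatting (see [format_g()]) and the
#' effective gravity sensed by cells.
#'
#' @param speeds_rpm Numeric vector of rotation speeds in rpm.
#' @param radius Radial position in m (default: the tissue-chamber radius of
#'   [organ_disc_geometry()]).
#' @return A tibble with columns `speed_rpm`, `omega_rad_s`, `rcf_g`,
#'   `rcf_label`, `effective_gravity_g`.
#' @examples
#' rcf_table(c(0, 100, 200, 500, 1000, 1500))
#' @export
rcf_table <- function(speeds_rpm, radius = organ_disc_geometry()$chamber_radius) {
  stopifnot(is.numeric(speeds_rpm), all(speeds_rpm >= 0))
  rcfs <- rcf(speeds_rpm, radius)
  tibble(
    speed_rpm = speeds_rpm,
    omega_rad_s = rpm_to_rad_s(speeds_rpm),
    rcf_g = rcfs,
    rcf_label = format_g(rcfs),
    effective_gravity_g = effective_gravity(rcfs)
  )
}
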