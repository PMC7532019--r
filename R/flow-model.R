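# Flow-vs-speed model variants.
#
# Four candidate models for the volumetric flow Q(omega) through the media
# channel:
#   hydrostatic_only  Q = C dp_h                       (constant in omega)
#   centrifugal_only  Q = C dp_c(omega)      = B omega^2
#   combined          Q = C (dp_c + dp_h)    = C dp_h + B omega^2
#   combined_pinned   Q = 0                  for omega <  omega0
#                     Q = B (omega^2 - omega0^2) for omega >= omega0
# with C the channel conductance and B = C * 1/2 rho (r2^2 - r1^2) the flow
# coefficient. The pinned variant treats capillary pinning at the exit port
# as a permanent backpressure p_v: the threshold omega0 satisfies
# omega0^2 = (p_v - p_h) / (1/2 rho (r2^2 - r1^2)), so for omega >= omega0
# the pinned flow equals C (dp_c + dp_h - p_v) exactly.

#' Flow coefficient B from geometry and fluid
#'
#' B = h^3 w / (12 eta L) * (1 - 0.630 h/w) * 1/2 rho (r2^2 - r1^2), the
#' proportionality between omega^2 and the centrifugally driven flow. It
#' depends only on channel dimensions and material properties. The returned
#' value carries a `provenance` attribute: with the bundled geometry it is
#' `"assumed"` because r1, r2 and L are assumptions, not printed dimensions.
#'
#' @param geom A [disc_geometry()] object.
#' @param fluid A [fluid_properties()] object.
#' @return B in (m^3/s) per (rad/s)^2, with a `provenance` attribute.
#' @examples
#' B_from_geometry(organ_disc_geometry(), water_properties(37))
#' @export
B_from_geometry <- function(geom, fluid) {
  stopifnot(inherits(geom, "disc_geometry"))
  C <- channel_conductance(geom, fluid)
  B <- C * 0.5 * fluid$density * (geom$r_outer^2 - geom$r_inner^2)
  prov <- geometry_provenance(geom)
  structure(B, provenance = weakest_provenance(
    prov[c("r_inner", "r_outer", "channel_height", "channel_width",
           "channel_length")]
  ))
}

#' Burst threshold speed from a burst pressure, and back
#'
#' The capillary valve bursts at the angular velocity where the driving
#' pressure first exceeds p_v: omega0^2 = (p_v - p_h) / (1/2 rho (r2^2 -
#' r1^2)). If p_v <= p_h the valve bursts at rest and omega0 = 0.
#' `burst_from_omega0()` is the exact algebraic inverse, p_v = p_h +
#' omega0^2 * 1/2 rho (r2^2 - r1^2).
#'
#' @param p_v Burst pressure in Pa.
#' @param p_h Hydrostatic pressure in Pa.
#' @param fluid A [fluid_properties()] object.
#' @param r1,r2 Inner and outer radii of the pumping liquid column in m,
#'   r2 > r1.
#' @param omega0 Threshold angular velocity in rad/s, >= 0.
#' @return `omega0_from_burst()`: omega0 in rad/s; `burst_from_omega0()`:
#'   p_v in Pa.
#' @examples
#' fl <- water_properties(37)
#' ph <- hydrostatic_pressure(fl, 8e-3)
#' omega0_from_burst(97, ph, fl, r1 = 10e-3, r2 = 45e-3) # ~4.5 rad/s
#' @export
omega0_from_burst <- function(p_v, p_h, fluid, r1, r2) {
  stopifnot(inherits(fluid, "fluid_properties"), is.numeric(p_v), is.numeric(p_h))
  if (any(r2 <= r1)) abort("`r2` must exceed `r1`: the pumping column needs positive radial extent.")
  sqrt(pmax(0, p_v - p_h) / (0.5 * fluid$density * (r2^2 - r1^2)))
}

#' @rdname omega0_from_burst
#' @export
burst_from_omega0 <- function(omega0, p_h, fluid, r1, r2) {
  stopifnot(inherits(fluid, "fluid_properties"), is.numeric(omega0))
  if (any(omega0 < 0)) abort("`omega0` must be >= 0.")
  if (any(r2 <= r1)) abort("`r2` must exceed `r1`.")
  p_h + omega0^2 * 0.5 * fluid$density * (r2^2 - r1^2)
}

#' Specify a flow-vs-speed model
#'
#' Builds one of the four model variants. For the geometry-based variants
#' (`hydrostatic_only`, `centrifugal_only`, `combined`) the flow coefficient
#' and hydrostatic baseline are derived from `geometry` and `fluid`. For
#' `combined_pinned` the coefficient `B` and threshold `omega0` may instead
#' be supplied directly (e.g. from a fit or a two-point calibration);
#' `geometry`/`fluid` then remain optional and are only needed to convert
#' the threshold to a burst pressure. The threshold may equivalently be
#' given as a burst pressure `p_v` (converted via [omega0_from_burst()],
#' which requires geometry and fluid).
#'
#' @param variant One of `"combined_pinned"`, `"combined"`,
#'   `"centrifugal_only"`, `"hydrostatic_only"`.
#' @param geometry Optional [disc_geometry()].
#' @param fluid Optional [fluid_properties()].
#' @param B Optional flow coefficient, > 0. Units set by `B_units`.
#' @param B_units `"ul_h_per_rad2_s2"` (default, the natural fitting scale)
#'   or `"si"` ((m^3/s)/(rad/s)^2).
#' @param omega0 Burst threshold in rad/s (combined_pinned only), >= 0.
#' @param p_v Alternative to `omega0`: burst pressure in Pa.
#' @return An object of class `flow_model`.
#' @examples
#' geom <- organ_disc_geometry(); fl <- water_properties(37)
#' flow_model("combined", geometry = geom, fluid = fl)
#' flow_model("combined_pinned", geometry = geom, fluid = fl, p_v = 97)
#' @export
flow_model <- function(variant = .flow_variants,
                       geometry = NULL, fluid = NULL,
                       B = NULL, B_units = c("ul_h_per_rad2_s2", "si"),
                       omega0 = NULL, p_v = NULL) {
  variant <- match.arg(variant)
  B_units <- match.arg(B_units)
  has_geom <- !is.null(geometry) && !is.null(fluid)
  if (!is.null(B)) {
    stopifnot(is.numeric(B), length(B) == 1, B > 0)
    B_si <- if (B_units == "si") B else ul_h_to_m3_s(B)
    B_provenance <- "fitted"
  } else {
    if (!has_geom) abort("Supply either `B` or both `geometry` and `fluid`.")
    Bg <- B_from_geometry(geometry, fluid)
    B_si <- as.numeric(Bg)
    B_provenance <- attr(Bg, "provenance")
  }
  q_h_si <- NA_real_
  if (has_geom) q_h_si <- channel_conductance(geometry, fluid) *
      hydrostatic_pressure(fluid, geometry$head_height)
  if (variant %in% c("hydrostatic_only", "combined") && !has_geom) {
    abort(sprintf("Variant `%s` needs `geometry` and `fluid` for the hydrostatic baseline.", variant))
  }
  if (variant == "combined_pinned") {
    if (!is.null(p_v)) {
      if (!is.null(omega0)) abort("Give `omega0` or `p_v`, not both.")
      if (!has_geom) abort("Converting `p_v` to a threshold needs `geometry` and `fluid`.")
      omega0 <- omega0_from_burst(
        p_v, hydrostatic_pressure(fluid, geometry$head_height),
        fluid, geometry$r_inner, geometry$r_outer
      )
    }
    omega0 <- omega0 %||% 0
    stopifnot(is.numeric(omega0), length(omega0) == 1, omega0 >= 0)
  } else {
    if (!is.null(omega0) || !is.null(p_v)) {
      abort("`omega0`/`p_v` only apply to the `combined_pinned` variant.")
    }
    omega0 <- 0
  }
  structure(
    list(variant = variant, B_si = B_si, omega0 = omega0,
         q_hydrostatic_si = q_h_si, geometry = geometry, fluid = fluid,
         B_provenance = B_provenance),
    class = "flow_model"
  )
}

#' Burst pressure implied by a pinned flow model
#'
#' Converts the fitted threshold omega0 back to a burst pressure via the
#' attached (or supplied) geometry and fluid. Declines with an error when no
#' radii are available: the conversion needs r1 and r2.
#'
#' @param model A `combined_pinned` [flow_model()].
#' @param geometry,fluid Optional overrides for the model's attached
#'   geometry and fluid.
#' @return Burst pressure p_v in Pa.
#' @export
model_burst_pressure <- function(model, geometry = NULL, fluid = NULL) {
  stopifnot(inherits(model, "flow_model"))
  if (model$variant != "combined_pinned") {
    abort("Only the `combined_pinned` variant has a burst pressure.")
  }
  geometry <- geometry %||% model$geometry
  fluid <- fluid %||% model$fluid
  if (is.null(geometry) || is.null(fluid)) {
    abort("Cannot convert the threshold to a burst pressure: no geometry/fluid available (r1, r2 required).")
  }
  burst_from_omega0(
    model$omega0, hydrostatic_pressure(fluid, geometry$head_height),
    fluid, geometry$r_inner, geometry$r_outer
  )
}

# core prediction in SI, vectorized over omega (rad/s)
predict_flow_si <- function(model, omega) {
  switch(model$variant,
    hydrostatic_only = rep(model$q_hydrostatic_si, length(omega)),
    centrifugal_only = model$B_si * omega^2,
    combined = model$q_hydrostatic_si + model$B_si * omega^2,
    combined_pinned = ifelse(omega < model$omega0, 0,
                             model$B_si * (omega^2 - model$omega0^2))
  )
}

#' Predict flow over a set of rotation speeds
#'
#' Evaluates the model variant at each speed. Predictions carry the
#' provenance of the model's flow coefficient (`"fitted"` when calibrated
#' against measurements, otherwise the weakest provenance of the geometry
#' fields it was derived from — `"assumed"` for the bundled geometry).
#'
#' @param model A [flow_model()].
#' @param speeds_rpm Numeric vector of rotation speeds in rpm, or a data
#'   frame with a `speed_rpm` column (extra columns are preserved).
#' @return A tibble with columns `speed_rpm`, `omega_rad_s`, `flow_ul_h`
#'   and `provenance`.
#' @examples
#' geom <- organ_disc_geometry(); fl <- water_properties(37)
#' m <- flow_model("combined_pinned", geometry = geom, fluid = fl, p_v = 97)
#' predict_flow(m, c(0, 50, 100, 150, 200))
#' @export
predict_flow <- function(model, speeds_rpm) {
  stopifnot(inherits(model, "flow_model"))
  if (is.data.frame(speeds_rpm)) {
    out <- as_tibble(speeds_rpm)
    if (!"speed_rpm" %in% names(out)) abort("Data frame input needs a `speed_rpm` column.")
  } else {
    stopifnot(is.numeric(speeds_rpm))
    out <- tibble(speed_rpm = as.numeric(speeds_rpm))
  }
  if (any(out$speed_rpm < 0)) abort("Speeds must be >= 0 rpm.")
  omega <- rpm_to_rad_s(out$speed_rpm)
  out$omega_rad_s <- omega
  out$flow_ul_h <- m3_s_to_ul_h(predict_flow_si(model, omega))
  out$provenance <- model$B_provenance
  out
}

#' Rotation speed needed for a target flow
#'
#' Analytic inversion of the model variant (no numeric root finding):
#' for the pinned model omega = sqrt(Q/B + omega0^2); for the combined
#' model the hydrostatic baseline is subtracted first and targets below it
#' are unreachable; under `hydrostatic_only` the flow does not depend on
#' speed at all, so any speed-resolved target is an error.
#'
#' @param model A [flow_model()].
#' @param target_ul_h Target flow in ul/h, >= 0 (vectorized).
#' @return Speed in rpm. A target of 0 under a pinned model returns the
#'   canonical 0 rpm (any speed up to the threshold gives zero flow).
#' @examples
#' geom <- organ_disc_geometry(); fl <- water_properties(37)
#' m <- flow_model("combined_pinned", geometry = geom, fluid = fl, p_v = 97)
#' speed_for_flow(m, 97)
#' @export
speed_for_flow <- function(model, target_ul_h) {
  stopifnot(inherits(model, "flow_model"), is.numeric(target_ul_h))
  if (any(target_ul_h < 0)) abort("`target_ul_h` must be >= 0.")
  q <- ul_h_to_m3_s(target_ul_h)
  omega <- switch(model$variant,
    hydrostatic_only = abort("Target unreachable by speed: under `hydrostatic_only` the flow does not depend on rotation speed."),
    centrifugal_only = sqrt(q / model$B_si),
    combined = {
      if (any(q < model$q_hydrostatic_si - 1e-300)) {
        abort(sprintf(
          "Target unreachable: the combined model never flows below its hydrostatic baseline of %.3g ul/h.",
          m3_s_to_ul_h(model$q_hydrostatic_si)
        ))
      }
      sqrt(pmax(0, q - model$q_hydrostatic_si) / model$B_si)
    },
    combined_pinned = ifelse(q == 0, 0, sqrt(q / model$B_si + model$omega0^2))
  )
  rad_s_to_rpm(omega)
}

#' @export
print.flow_model <- function(x, ...) {
  cat(sprintf("<flow_model: %s>\n", x$variant))
  cat(sprintf("  B       %.4g ul/h per (rad/s)^2  [%s]\n",
              m3_s_to_ul_h(x$B_si), x$B_provenance))
  if (x$variant == "combined_pinned") {
    cat(sprintf("  omega0  %.4g rad/s (%.4g rpm)\n", x$omega0,
                rad_s_to_rpm(x$omega0)))
    pv <- tryCatch(model_burst_pressure(x), error = function(e) NULL)
    if (!is.null(pv)) cat(sprintf("  p_v     %.4g Pa (via attached geometry)\n", pv))
  }
  if (!is.na(x$q_hydrostatic_si) && x$variant %in% c("combined", "hydrostatic_only")) {
    cat(sprintf("  Q_h     %.4g ul/h (hydrostatic baseline)\n",
                m3_s_to_ul_h(x$q_hydrostatic_si)))
  }
  invisible(x)
}

#' Serialize a flow model to YAML, and back
#'
#' Writes the variant, flow coefficient and threshold as full-precision
#' `{value, unit, provenance}` nodes in the same config dialect as
#' [write_geometry_config()]. The attached geometry/fluid are not embedded;
#' re-attach them on read when burst-pressure conversion is needed.
#'
#' @param model A [flow_model()].
#' @param path File path.
#' @param geometry,fluid Optional [disc_geometry()] / [fluid_properties()]
#'   to attach on read.
#' @return `write_flow_model()`: `path`, invisibly. `read_flow_model()`: a
#'   [flow_model()].
#' @export
write_flow_model <- function(model, path) {
  stopifnot(inherits(model, "flow_model"))
  doc <- list(flow_model = list(
    variant = model$variant,
    B = list(value = num_to_chr(model$B_si), unit = "m^3/s per (rad/s)^2",
             provenance = model$B_provenance),
    omega0 = list(value = num_to_chr(model$omega0), unit = "rad/s",
                  provenance = model$B_provenance)
  ))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_flow_model
#' @export
read_flow_model <- function(path, geometry = NULL, fluid = NULL) {
  doc <- yaml::read_yaml(path)
  m <- doc$flow_model
  if (is.null(m)) abort("Config has no `flow_model:` section.")
  variant <- m$variant
  B_si <- chr_to_num(m$B$value)
  omega0 <- chr_to_num(m$omega0$value)
  out <- flow_model(variant, geometry = geometry, fluid = fluid,
                    B = B_si, B_units = "si",
                    omega0 = if (variant == "combined_pinned") omega0 else NULL)
  out$B_provenance <- m$B$provenance %||% out$B_provenance
  out
}
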