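# Unit conventions: every internal computation is in SI base units
# (m, kg, s, Pa, m^3/s, rad/s). rpm, ul/h, g and mm appear only at the
# interfaces and in display helpers.

#' Standard gravity
#'
#' The conventional standard acceleration of free fall, used to express
#' centrifugal accelerations as relative centrifugal force (RCF, in
#' multiples of g).
#'
#' @format A single number, 9.80665 m/s^2.
#' @export
G0 <- 9.80665

#' Convert rotation speed between rpm and angular velocity
#'
#' `rpm_to_rad_s()` applies omega = 2*pi*speed/60; `rad_s_to_rpm()` is its
#' exact inverse. Both are vectorized.
#'
#' @param speed_rpm Rotation speed in revolutions per minute.
#' @param omega Angular velocity in rad/s.
#' @return Numeric vector of the converted quantity.
#' @examples
#' rpm_to_rad_s(100) # 10.47 rad/s
#' rad_s_to_rpm(rpm_to_rad_s(250)) # 250
#' @export
rpm_to_rad_s <- function(speed_rpm) 2 * pi * speed_rpm / 60

#' @rdname rpm_to_rad_s
#' @export
rad_s_to_rpm <- function(omega) omega * 60 / (2 * pi)

# 1 m^3/s = 3.6e12 ul/h
UL_H_PER_M3_S <- 3.6e12

#' Convert volumetric flow between SI and microlitres per hour
#'
#' @param q_si Flow in m^3/s.
#' @param q_ul_h Flow in ul/h.
#' @return Numeric vector of the converted flow.
#' @export
m3_s_to_ul_h <- function(q_si) q_si * UL_H_PER_M3_S

#' @rdname m3_s_to_ul_h
#' @export
ul_h_to_m3_s <- function(q_ul_h) q_ul_h / UL_H_PER_M3_S

#' Format a relative centrifugal force the way instrument protocols print it
#'
#' Below 10 g two significant figures are kept, between 10 and 1000 g one
#' decimal, and at or above 1000 g the nearest integer. This matches the
#' usual granularity of spin-protocol tables (e.g. 0.46 g, 1.9 g, 11.6 g,
#' 46.4 g, 104.4 g, 743 g).
#'
#' @param rcf Relative centrifugal force in multiples of g (numeric vector).
#' @return Character vector of formatted values (no unit suffix).
#' @examples
#' format_g(c(0.4641, 1.856, 11.60, 104.42, 742.5))
#' @export
format_g <- function(rcf) {
  stopifnot(is.numeric(rcf), all(rcf >= 0 | is.na(rcf)))
  vapply(rcf, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x < 10) format(signif(x, 2), trim = TRUE, scientific = FALSE)
    else if (x < 1000) sprintf("%.1f", x)
    else sprintf("%.0f", x)
  }, character(1))
}

# full-precision numeric <-> string round trip for YAML configs
num_to_chr <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
chr_to_num <- function(x) suppressWarnings(as.numeric(x))
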