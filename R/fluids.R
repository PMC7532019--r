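#' Fluid properties of the working liquid
#'
#' Bundles the density, dynamic viscosity and surface tension that enter the
#' pressure and flow laws. All values are SI; the temperature is an
#' annotation and enters no formula.
#'
#' @param density Density rho in kg/m^3. Must lie in (500, 2000), a sanity
#'   band covering aqueous media.
#' @param viscosity Dynamic viscosity eta in Pa*s, strictly positive.
#' @param surface_tension Surface tension sigma in N/m, strictly positive.
#' @param temperature Temperature in degrees C (annotation only).
#' @return An object of class `fluid_properties` (a named list).
#' @seealso [water_properties()] for the built-in water table.
#' @examples
#' fluid_properties(993.3, 6.92e-4, 0.070, temperature = 37)
#' @export
fluid_properties <- function(density, viscosity, surface_tension,
                             temperature = NA_real_) {
  stopifnot(
    is.numeric(density), length(density) == 1, is.finite(density),
    is.numeric(viscosity), length(viscosity) == 1, is.finite(viscosity),
    is.numeric(surface_tension), length(surface_tension) == 1,
    is.finite(surface_tension)
  )
  if (density <= 500 || density >= 2000) {
    abort(sprintf(
      "`density` = %g kg/m^3 is outside the (500, 2000) sanity band for aqueous working liquids.",
      density
    ))
  }
  if (viscosity <= 0) abort("`viscosity` must be strictly positive (Pa*s).")
  if (surface_tension <= 0) abort("`surface_tension` must be strictly positive (N/m).")
  structure(
    list(
      density = density, viscosity = viscosity,
      surface_tension = surface_tension, temperature = temperature
    ),
    class = "fluid_properties"
  )
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat("<fluid_properties>\n")
  cat(sprintf("  density         %g kg/m^3\n", x$density))
  cat(sprintf("  viscosity       %g Pa*s\n", x$viscosity))
  cat(sprintf("  surface tension %g N/m\n", x$surface_tension))
  if (!is.na(x$temperature)) cat(sprintf("  temperature     %g degC\n", x$temperature))
  invisible(x)
}

# Handbook values for liquid water at the tabulated temperatures.
# Fixed table by design: acceptance-grade pressure numbers must not move
# with an interpolation scheme.
.water_table <- list(
  `4`  = c(density = 1000.0, viscosity = 1.567e-3, surface_tension = 0.0750),
  `20` = c(density = 998.2,  viscosity = 1.002e-3, surface_tension = 0.0728),
  `25` = c(density = 997.0,  viscosity = 0.890e-3, surface_tension = 0.0720),
  `37` = c(density = 993.3,  viscosity = 0.692e-3, surface_tension = 0.0700)
)

#' Properties of liquid water at tabulated temperatures
#'
#' Returns handbook values of density, dynamic viscosity and surface tension
#' for de-ionized water at one of the temperatures relevant to cell-culture
#' workflows: 4, 20, 25 or 37 degrees C (incubator temperature). Values come
#' from a small fixed table; untabulated temperatures are an error rather
#' than silently interpolated, so downstream pressure numbers are
#' reproducible to the digit.
#'
#' @param temperature Temperature in degrees C; one of 4, 20, 25, 37.
#' @return A [fluid_properties()] object.
#' @examples
#' water_properties(37) # incubator temperature: rho 993.3, sigma 0.070
#' @export
water_properties <- function(temperature = 37) {
  stopifnot(is.numeric(temperature), length(temperature) == 1)
  if (temperature < 0 || temperature > 100) {
    abort("`temperature` must be in [0, 100] degC (liquid water).")
  }
  key <- as.character(temperature)
  if (!key %in% names(.water_table)) {
    abort(sprintf(
      "Unsupported temperature %g degC: the built-in water table covers %s degC only (no interpolation).",
      temperature, paste(names(.water_table), collapse = ", ")
    ))
  }
  p <- .water_table[[key]]
  fluid_properties(p[["density"]], p[["viscosity"]], p[["surface_tension"]],
                   temperature = temperature)
}
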