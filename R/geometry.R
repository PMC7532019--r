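#' Disc and reservoir geometry
#'
#' Describes the radial positions and channel/port dimensions of a
#' disc-shaped perfusion platform. All lengths are in metres (SI
#' throughout); conversion to mm happens only in display. Each field carries
#' a provenance tag (`"printed"`, `"derived"` or `"assumed"`) so that every
#' quantity computed downstream can be labelled with the provenance of its
#' weakest input.
#'
#' @param chamber_radius Radial position of the tissue-chamber centroid (m),
#'   the radius at which RCF on the cells is reported.
#' @param r_inner Effective inner radius of the pumping liquid column (m),
#'   taken at the middle of the inner reservoir compartment.
#' @param r_outer Radius of the media-channel outlet (m).
#' @param channel_height Media-channel height h (m).
#' @param channel_width Media-channel width w (m); the rectangular-channel
#'   flow law assumes h much smaller than w.
#' @param channel_length Media-channel length L (m).
#' @param port_diameter Diameter d of the circular reservoir ports (m); the
#'   exit port acts as a capillary burst valve.
#' @param head_height Fluid level H above the inlet, perpendicular to the
#'   disc plane (m); sets the hydrostatic pressure.
#' @param disc_radius Outer radius of the disc (m).
#' @param n_systems Number of independent perfusion systems on the disc.
#' @param chambers_per_system Tissue chambers supplied in-line per system.
#' @param provenance Named character vector overriding the default
#'   provenance tags for individual fields.
#' @return An object of class `disc_geometry` (a named list with a
#'   `provenance` attribute).
#' @seealso [organ_disc_geometry()] for the bundled default,
#'   [validate_geometry()] for invariant checking.
#' @export
disc_geometry <- function(chamber_radius,
                          r_inner,
                          r_outer,
                          channel_height,
                          channel_width,
                          channel_length,
                          port_diameter,
                          head_height,
                          disc_radius = 0.05,
                          n_systems = 4L,
                          chambers_per_system = 5L,
                          provenance = NULL) {
  geom <- list(
    chamber_radius = as.numeric(chamber_radius),
    r_inner = as.numeric(r_inner),
    r_outer = as.numeric(r_outer),
    channel_height = as.numeric(channel_height),
    channel_width = as.numeric(channel_width),
    channel_length = as.numeric(channel_length),
    port_diameter = as.numeric(port_diameter),
    head_height = as.numeric(head_height),
    disc_radius = as.numeric(disc_radius),
    n_systems = as.integer(n_systems),
    chambers_per_system = as.integer(chambers_per_system)
  )
  prov <- .default_provenance
  if (!is.null(provenance)) {
    bad <- setdiff(names(provenance), names(prov))
    if (length(bad) > 0) {
      abort(paste0("Unknown provenance field(s): ", paste(bad, collapse = ", ")))
    }
    stopifnot(all(provenance %in% c("printed", "derived", "assumed")))
    prov[names(provenance)] <- provenance
  }
  structure(geom, provenance = prov, class = "disc_geometry")
}

#' Default disc geometry of the reference platform
#'
#' The bundled geometry: a 10 cm disc carrying 4 independent systems of 5
#' in-line tissue chambers, media channels 1.4 mm wide and 75 um high,
#' 2 mm circular reservoir ports and an 8 mm fluid head. The chamber radius
#' (41.5 mm) is back-derived from the loading anchor 1000 rpm = 46.4 g and
#' tagged `"derived"`; the pumping-column radii (10 mm inner, 45 mm outer)
#' and the 100 mm channel length are not printed in any protocol and are
#' tagged `"assumed"` — every flow prediction that uses them inherits that
#' tag.
#'
#' @return A [disc_geometry()] object.
#' @examples
#' geom <- organ_disc_geometry()
#' validate_geometry(geom) # no findings
#' @export
organ_disc_geometry <- function() {
  disc_geometry(
    chamber_radius = 41.5e-3,
    r_inner = 10e-3,
    r_outer = 45e-3,
    channel_height = 75e-6,
    channel_width = 1.4e-3,
    channel_length = 100e-3,
    port_diameter = 2e-3,
    head_height = 8e-3,
    disc_radius = 0.05,
    n_systems = 4L,
    chambers_per_system = 5L
  )
}

#' Provenance tags of a geometry
#'
#' @param geom A [disc_geometry()] object.
#' @return Named character vector of `"printed"`, `"derived"` or `"assumed"`
#'   per field.
#' @export
geometry_provenance <- function(geom) {
  stopifnot(inherits(geom, "disc_geometry"))
  attr(geom, "provenance")
}

# weakest provenance among a set of tags: printed < derived < assumed
weakest_provenance <- function(tags) {
  order <- c("printed", "derived", "assumed")
  order[max(match(tags, order))]
}

#' Check a geometry against its physical invariants
#'
#' Runs every invariant the downstream formulas rely on and returns the
#' violations as data, not conditions: an empty tibble means the geometry is
#' usable. Aspect ratios h/w above 0.5 produce a warning-level finding
#' (the 0.630 aspect-ratio correction of the rectangular-channel flow law
#' degrades there) rather than an error.
#'
#' @param geom A [disc_geometry()] object.
#' @return A tibble with columns `field`, `level` (`"error"` or
#'   `"warning"`) and `message`; zero rows when all invariants hold.
#' @examples
#' validate_geometry(organ_disc_geometry())
#' @export
validate_geometry <- function(geom) {
  stopifnot(inherits(geom, "disc_geometry"))
  findings <- list()
  add <- function(field, level, message) {
    findings[[length(findings) + 1]] <<- tibble(
      field = field, level = level, message = message
    )
  }
  for (f in .geometry_length_fields) {
    v <- geom[[f]]
    if (!is.finite(v) || v <= 0) {
      add(f, "error", sprintf("%s must be a positive, finite length (got %g m)", f, v))
    }
  }
  if (is.finite(geom$r_inner) && is.finite(geom$r_outer) &&
      geom$r_inner >= geom$r_outer) {
    add("r_inner", "error", sprintf(
      "r_inner (%g m) must be smaller than r_outer (%g m): the pumping liquid column would be degenerate",
      geom$r_inner, geom$r_outer
    ))
  }
  if (is.finite(geom$r_outer) && is.finite(geom$disc_radius) &&
      geom$r_outer > geom$disc_radius) {
    add("r_outer", "error", sprintf(
      "r_outer (%g m) lies outside the disc (radius %g m)",
      geom$r_outer, geom$disc_radius
    ))
  }
  if (is.finite(geom$channel_height) && is.finite(geom$channel_width)) {
    ar <- geom$channel_height / geom$channel_width
    if (ar > 1) {
      add("channel_height", "error", sprintf(
        "channel_height exceeds channel_width (h/w = %.3g): the flow law requires h <= w", ar
      ))
    } else if (ar > 0.5) {
      add("channel_height", "warning", sprintf(
        "aspect ratio h/w = %.3g > 0.5: the (1 - 0.630 h/w) correction of the rectangular-channel flow law loses accuracy", ar
      ))
    }
  }
  if (geom$n_systems < 1L || geom$chambers_per_system < 1L) {
    add("n_systems", "error", "n_systems and chambers_per_system must both be >= 1")
  }
  if (length(findings) == 0) {
    return(tibble(field = character(), level = character(), message = character()))
  }
  dplyr::bind_rows(findings)
}

#' @export
print.disc_geometry <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("<disc_geometry>\n")
  mm <- function(f) sprintf("%-15s %8.4g mm  [%s]", f, x[[f]] * 1e3, prov[[f]])
  for (f in .geometry_length_fields) cat(" ", mm(f), "\n")
  cat(sprintf("  %-15s %8d     [%s]\n", "n_systems", x$n_systems, prov[["n_systems"]]))
  cat(sprintf("  %-15s %8d     [%s]\n", "chambers/system", x$chambers_per_system,
              prov[["chambers_per_system"]]))
  cat(sprintf("  total chambers  %8d\n", x$n_systems * x$chambers_per_system))
  invisible(x)
}
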