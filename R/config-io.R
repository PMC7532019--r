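# YAML configs for geometry and fluids. Every field is written as
# {value, unit, provenance}; numeric values are serialized as %.17g strings
# so a write/read round trip reproduces doubles bit-exactly (yaml's default
# emitter truncates).

field_node <- function(value, unit, provenance) {
  list(value = num_to_chr(value), unit = unit, provenance = provenance)
}

#' Write a geometry (and optionally fluid) configuration to YAML
#'
#' Each field is emitted as a `{value, unit, provenance}` node. Values are
#' stored as full-precision strings, so [read_geometry_config()] reproduces
#' every number bit-exactly.
#'
#' @param geom A [disc_geometry()] object.
#' @param path File path to write.
#' @param fluid Optional [fluid_properties()] object to embed.
#' @param metadata Optional named list of free-form annotations (written
#'   verbatim under `metadata:`).
#' @return `path`, invisibly.
#' @seealso [read_geometry_config()]
#' @export
write_geometry_config <- function(geom, path, fluid = NULL, metadata = NULL) {
  stopifnot(inherits(geom, "disc_geometry"))
  prov <- attr(geom, "provenance")
  g <- lapply(names(.geometry_units), function(f) {
    if (f %in% c("n_systems", "chambers_per_system")) {
      list(value = geom[[f]], unit = "count", provenance = unname(prov[[f]]))
    } else {
      field_node(geom[[f]], .geometry_units[[f]], unname(prov[[f]]))
    }
  })
  names(g) <- names(.geometry_units)
  doc <- list(geometry = g)
  if (!is.null(fluid)) {
    stopifnot(inherits(fluid, "fluid_properties"))
    fl <- list(
      density = field_node(fluid$density, .fluid_units[["density"]], "printed"),
      viscosity = field_node(fluid$viscosity, .fluid_units[["viscosity"]], "printed"),
      surface_tension = field_node(fluid$surface_tension,
                                   .fluid_units[["surface_tension"]], "printed"),
      temperature = field_node(fluid$temperature, .fluid_units[["temperature"]], "printed")
    )
    doc$fluid <- fl
  }
  if (!is.null(metadata)) doc$metadata <- metadata
  yaml::write_yaml(doc, path)
  invisible(path)
}

read_field <- function(node, field, expected_unit) {
  if (is.null(node)) abort(sprintf("Config is missing field `%s`.", field))
  if (!identical(node$unit, expected_unit)) {
    abort(sprintf("Field `%s` must be in `%s` (config says `%s`).",
                  field, expected_unit, node$unit %||% "<missing>"))
  }
  chr_to_num(node$value)
}

#' Read a geometry/fluid configuration written by [write_geometry_config()]
#'
#' @param path Path to the YAML file.
#' @return A list with elements `geometry` ([disc_geometry()]), `fluid`
#'   ([fluid_properties()] or `NULL`) and `metadata` (list or `NULL`).
#' @examples
#' cfg <- read_geometry_config(
#'   system.file("extdata", "organ_disc_default.yaml", package = "discflow")
#' )
#' cfg$geometry
#' @export
read_geometry_config <- function(path) {
  doc <- yaml::read_yaml(path)
  g <- doc$geometry
  if (is.null(g)) abort("Config has no `geometry:` section.")
  lengths <- lapply(.geometry_length_fields, function(f) read_field(g[[f]], f, "m"))
  names(lengths) <- .geometry_length_fields
  prov <- vapply(names(.geometry_units), function(f) {
    g[[f]]$provenance %||% .default_provenance[[f]]
  }, character(1))
  geom <- disc_geometry(
    chamber_radius = lengths$chamber_radius,
    r_inner = lengths$r_inner,
    r_outer = lengths$r_outer,
    channel_height = lengths$channel_height,
    channel_width = lengths$channel_width,
    channel_length = lengths$channel_length,
    port_diameter = lengths$port_diameter,
    head_height = lengths$head_height,
    disc_radius = lengths$disc_radius,
    n_systems = as.integer(g$n_systems$value),
    chambers_per_system = as.integer(g$chambers_per_system$value),
    provenance = prov
  )
  fluid <- NULL
  if (!is.null(doc$fluid)) {
    fl <- doc$fluid
    fluid <- fluid_properties(
      density = read_field(fl$density, "density", "kg/m^3"),
      viscosity = read_field(fl$viscosity, "viscosity", "Pa*s"),
      surface_tension = read_field(fl$surface_tension, "surface_tension", "N/m"),
      temperature = read_field(fl$temperature, "temperature", "degC")
    )
  }
  list(geometry = geom, fluid = fluid, metadata = doc$metadata)
}
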