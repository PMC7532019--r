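# Internal constants shared across modules (this file sorts first in the
# default collation order).

.geometry_length_fields <- c(
  "chamber_radius", "r_inner", "r_outer", "channel_height", "channel_width",
  "channel_length", "port_diameter", "head_height", "disc_radius"
)

.default_provenance <- c(
  chamber_radius = "derived",   # back-derived from the 1000 rpm <-> 46.4 g anchor
  r_inner = "assumed",          # middle of inner reservoir compartment, not printed
  r_outer = "assumed",          # media-channel outlet radius, not printed
  channel_height = "printed",
  channel_width = "printed",
  channel_length = "assumed",   # media-channel length, not printed
  port_diameter = "printed",
  head_height = "printed",
  disc_radius = "printed",
  n_systems = "printed",
  chambers_per_system = "printed"
)

.geometry_units <- c(
  stats::setNames(rep("m", length(.geometry_length_fields)), .geometry_length_fields),
  n_systems = "count", chambers_per_system = "count"
)

.fluid_units <- c(
  density = "kg/m^3", viscosity = "Pa*s", surface_tension = "N/m",
  temperature = "degC"
)

.flow_variants <- c("combined_pinned", "combined", "centrifugal_only",
                    "hydrostatic_only")
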