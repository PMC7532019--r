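geometry:
  chamber_radius:
    value: '0.041500000000000002'
    unit: m
    provenance: derived
  r_inner:
    value: '0.01'
    unit: m
    provenance: assumed
  r_outer:
    value: '0.044999999999999998'
    unit: m
    provenance: assumed
  channel_height:
    value: '7.4999999999999993e-05'
    unit: m
    provenance: printed
  channel_width:
    value: '0.0014'
    unit: m
    provenance: printed
  channel_length:
    value: '0.10000000000000001'
    unit: m
    provenance: assumed
  port_diameter:
    value: '0.002'
    unit: m
    provenance: printed
  head_height:
    value: '0.0080000000000000002'
    unit: m
    provenance: printed
  disc_radius:
    value: '0.050000000000000003'
    unit: m
    provenance: printed
  n_systems:
    value: 4
    unit: count
    provenance: printed
  chambers_per_system:
    value: 5
    unit: count
    provenance: printed
fluid:
  density:
    value: '993.29999999999995'
    unit: kg/m^3
    provenance: printed
  viscosity:
    value: '0.00069200000000000002'
    unit: Pa*s
    provenance: printed
  surface_tension:
    value: '0.070000000000000007'
    unit: N/m
    provenance: printed
  temperature:
    value: '37'
    unit: degC
    provenance: printed
metadata:
  platform: rotation-perfused organ disc, 10 cm diameter
  tissue_layer_um: 175.0
  membrane_pore_um: 3.0
  membrane_thickness_um: 15.0
  port_layer_mm: 2.0
  notes: chamber_radius back-derived from the 1000 rpm = 46.4 g loading anchor; r_inner/r_outer/channel_length
    are assumed values for the pumping column and media channel
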