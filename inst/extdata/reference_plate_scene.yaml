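transducer:
  frequency_hz: 900000.0
  aperture_mm: 100.0
  focal_length_mm: 80.0
  hole_mm: 50.0
  surface_pressure_pa: 5525.9
water:
  density_kg_m3: 998.2
  sound_speed_m_s: 1482.0
  absorption_np_m_mhz: 0.02
  nonlinearity: 3.5
  label: water
domain:
  r_mm: 50.2233333
  z_mm: 100.035
grid:
  mode: axisymmetric
  dx_mm: 0.4116667
  dt_ns: 55.5555556
plate:
  thickness_mm: 8.0
  curvature_radius_mm: 60.0
  standoff_mm: 10.0
  material:
    density_kg_m3: 1203.0
    sound_speed_m_s: 2600.0
    absorption_np_m_mhz: 18.0
    nonlinearity: 4.4
    label: acrylic
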