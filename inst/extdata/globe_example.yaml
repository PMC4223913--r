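model: globe
geometry:
  cct_um: 865
  anterior_curvature_mm: 6.8
  posterior_curvature_mm: 5.57
  cornea_diameter_mm: 10.40
  sclera_diameter_mm: 19
  sclera_thickness_mm: 1.0
materials:
  E_anterior_kPa: 24.8
  E_posterior_kPa: 19.8
  limbus_E_kPa: 37.2
  sclera_E_kPa: 744
  density_kg_m3: 1160
  nu: 0.499
  prony:
    p: 0.1
    T_ms: 1
fluid:
  density_kg_m3: 1000
  sonic_velocity_m_s: 1480
  viscosity: 8.94e-4
  fsi_range_mm: 2.8
loading:
  iop_kPa: 2.2
  prestress: none
  excitation: base
  holder_distance_mm: 5
  holder_width_mm: 1
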