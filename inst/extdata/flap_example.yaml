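model: flap
geometry:
  diameter_mm: 4.0
  thickness_um: 120
materials:
  E_kPa: 14.58
  density_kg_m3: 1160
  nu: 0.499
  prony:
    p: 0.1
    T_ms: 1
loading:
  prestress_kPa: 0.67
  excitation: base
mesh:
  n_radial: 27
  n_thickness: 2
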