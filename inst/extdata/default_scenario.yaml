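# Reference extraction scenario: 3 cm clot, 3 partitions, total occlusion
# of a 2.5 mm cerebral artery, aspiration ramped to -200 kPa over 1 s.
artery:
  diameter: {value: 2.5, unit: mm}
  occlusion: {value: 100, unit: percent}
clot:
  length: {value: 3.0, unit: cm}
  diameter: {value: 2.5, unit: mm}
  total_mass: {value: 1.25, unit: g}
  n_partitions: 3
  fp: 0.96
  mean_platelet_area: {value: 5.31e-6, unit: mm^2}
  platelet_bond_force: {value: 32.0e-9, unit: "N"}
  sphere_spacing: {value: 0.1, unit: mm}
mechanics:
  K_union: {value: 1.91, unit: N/m}
  R_union: {value: 0.035, unit: N.s/m}
  R_static: {value: 2.5e-6, unit: N.s/m}
  dynamic_friction_mode: stokes_quadratic
  R_dynamic: {value: 2.5e-7, unit: N.s/m}
  C_form: 1.2
  rho_blood: {value: 1060, unit: kg/m^3}
  K_wall: {value: 1.0e+10, unit: N/m}
  R_wall: {value: 1.0e+9, unit: N.s/m}
  F_move_threshold: {value: 0.01, unit: "N"}
forcing:
  aspiration:
    type: ramp
    p_start: {value: 0, unit: kPa}
    p_end: {value: -200, unit: kPa}
    t_ramp: {value: 1, unit: s}
  cardiac:
    enabled: false
    period: {value: 1, unit: s}
    switch_time: {value: 0.32, unit: s}
    mode: modulation
simulation:
  model_variant: extended
  extraction_distance: {value: 2.5, unit: mm}
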