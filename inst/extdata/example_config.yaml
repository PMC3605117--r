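geometry:
  r_myo_outer: 0.16
  wall_thickness: 0.01
  r_fetus: 0.12
  r_abdomen: 0.21
  abdomen_offset:
  - -0.03
  - 0.0
  - 0.0
  lambda_vernix: 0.0
ionic: []
myocyte: []
conductivity: []
alpha: 0.7853982
c_target: 0.0115
pacemakers:
- nu: 2.0
  t_on: 0.0
  t_off: 0.1
  r_min: 0.15
  r_max: 0.16
  z_min: 0.15
solver:
  dt: 0.02
  t_end: 120.0
  output_stride: 50
mesh:
  resolution: 0.03
  dimension: 3
sensors:
  nsub: 2
  cap_axis:
  - 1.0
  - 0.0
  - 0.0
  cap_angle: 3.1415927
probe_elevation:
- 0.6283185
- 1.4137167
- 2.1991149
seed: 1
out_dir: uterowave_run
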