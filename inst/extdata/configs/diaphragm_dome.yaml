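# Isolated diaphragm contraction on a synthetic dome: radial fibres from
# the central tendon, crural-like dorsal extension, flattened anterior
# profile, compliant rim, abdominal and pleural pressure ramps (pressures
# in MPa: 2 kPa = 2e-3).
mesh:
  generator: dome
  args: {R: 45, thickness: 5, tendon_fraction: 0.35, n_ref: 2,
         rim_extend_deg: 20, sternal_shear: 0.3}
materials:
  diaphragm:
    model: muscle
    T0M: 0.3
    c: 0.009348
    b: 1.4939
    fl_curve: diaphragm
  central_tendon:
    model: isotropic
    mu: 5.18
    lam: 10.05
springs:
  - {nodes: rim, k: 20}
pressures:
  - {face_set: abdominal, from: 0, to: 2.0e-3}
  - {face_set: pleural, from: -0.5e-3, to: -0.75e-3}
activation:
  fields:
    - {type: diaphragm, level: 1.0}
  waveform: {type: ramp}
  span: [0, 1]
options:
  stab: 0.01
solver:
  n_increments: 12
  max_iters: 40
  stall_tol: 1.0e-3
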