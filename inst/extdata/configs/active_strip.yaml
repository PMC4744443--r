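# Active uniaxial strip: fibres along x, both ends clamped axially,
# activation ramped to full over the run. The reaction at the clamped end
# approaches T0M * f_CE(1) * cross-section.
mesh:
  generator: strip
  args: {L: 6, W: 2, H: 2, nx: 6, ny: 2, nz: 2, fiber_axis: x,
         region: muscle}
materials:
  muscle:
    model: muscle
    T0M: 0.3
    a: 12.43
    A: 0.28
    c: 0.009348
    b: 1.4939
    fl_curve: intercostal
dirichlet:
  - {nodes: x0, comps: [1]}
  - {nodes: x1, comps: [1]}
  - {nodes: y0, comps: [2]}
  - {nodes: z0, comps: [3]}
activation:
  fields:
    - {type: uniform, level: 1.0}
  waveform: {type: ramp}
  span: [0, 1]
solver:
  n_increments: 4
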