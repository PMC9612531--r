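# Desk-scale example build: two levels per axis, 2-D scenes.
# Full-scale builds raise the level counts and set scene.ndim: 3 with
# scene.spacing: 5.0e-4 (the 256^3 configuration).
grid:
  frequency: [350.0e+3, 500.0e+3]   # Hz
  thickness: [0.0, 2.25e-3]         # m
  trajectory: [75.0, 90.0]          # degrees (90 = normal incidence)
  depth: [2.25e-2, 3.0e-2]          # m
  diameter: [1.5e-2, 1.8e-2]        # m
scene:
  spacing: 7.5e-4                   # m
  ndim: 2
  pml_size: 10
  pml_alpha: 2.0
solver:
  cfl: 0.3
  ramp_cycles: 3
output: toy_surrogate.rds
checkpoint: toy_surrogate_ckpt.rds
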