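# Example configuration: any entry overrides the corresponding default.
# Sections map to constructors: arm -> arm_params(), muscle -> muscle_spec().
arm:
  dt: 0.002
  limit_stiffness: 10000
  limit_damping: 100
muscle:
  v_max: 1.6
  b: [1.3, -1.3, 0.53]
  d: [4, 1.8, 30.24]
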