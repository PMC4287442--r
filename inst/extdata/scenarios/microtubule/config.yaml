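name: microtubule
bindings:
  v:
    offset:
    - 0.0
    - 0.0
    - 1.0
    axis:
    - 0.0
    - 0.0
    - 1.0
    angle: 0.0
    branch_start: no
  h:
    offset:
    - -0.2393157
    - 0.9709418
    - -0.8461538
    axis:
    - 0.0
    - 0.0
    - 1.0
    angle: 27.6923077
    branch_start: no
agents:
  tubulin:
    D: 1.0
    affinity: 80.0
    geometry: sphere
    D_rot: 1.0
densities:
  tubulin:
    t: 0.0
    density: 0.0125
config:
  t_max: 5.0
branch_rules: []
root:
  position:
  - 0.0
  - 0.0
  - 0.0
  orientation:
  - 1.0
  - 0.0
  - 0.0
  - 0.0
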