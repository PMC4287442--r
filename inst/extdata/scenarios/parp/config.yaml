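name: parp
bindings:
  g:
    offset:
    - 0.0
    - 0.0
    - 1.0
    axis:
    - 0.0
    - 0.0
    - 1.0
    angle: 30.0
    branch_start: no
  b:
    offset:
    - 0.7
    - 0.0
    - 0.7
    axis:
    - 0.0
    - 1.0
    - 0.0
    angle: 65.0
    branch_start: yes
agents:
  NAD:
    D: 1.0
    affinity: 80.0
    geometry: sphere
    D_rot: 1.0
densities:
  NAD:
    t: 0.0
    density: 0.0125
config:
  t_max: 5.0
branch_rules:
- p1
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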