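name: showcase
bindings:
  g:
    offset:
    - 0.0
    - 0.0
    - 1.0
    axis:
    - 0.25
    - 0.0
    - 0.97
    angle: 40.0
    branch_start: no
  l:
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
  u1:
    offset:
    - 0.8660254
    - 0.0
    - 0.5
    axis:
    - 0.0
    - 1.0
    - 0.0
    angle: 60.0
    branch_start: yes
  u2:
    offset:
    - 0.2676166
    - 0.8236391
    - 0.5
    axis:
    - -0.4118881
    - 0.5669153
    - 0.713411
    angle: 91.0449756
    branch_start: yes
  u3:
    offset:
    - -0.7006293
    - 0.509037
    - 0.5
    axis:
    - -0.4935295
    - 0.1603575
    - 0.8548182
    angle: 148.9550244
    branch_start: yes
  u4:
    offset:
    - -0.7006293
    - -0.509037
    - 0.5
    axis:
    - 0.4935295
    - 0.1603575
    - -0.8548182
    angle: 148.9550244
    branch_start: yes
  u5:
    offset:
    - 0.2676166
    - -0.8236391
    - 0.5
    axis:
    - 0.4118881
    - 0.5669153
    - -0.713411
    angle: 91.0449756
    branch_start: yes
agents:
  sphereunit:
    D: 1.0
    affinity: 80.0
    geometry: sphere
    D_rot: 1.0
  cubeunit:
    D: 1.0
    affinity: 80.0
    geometry: cube
    D_rot: 1.0
  cylunit:
    D: 1.0
    affinity: 80.0
    geometry: cylinder
    D_rot: 1.0
densities:
  sphereunit:
    t: 0.0
    density: 0.0125
  cubeunit:
    t: 0.0
    density: 0.0125
  cylunit:
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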