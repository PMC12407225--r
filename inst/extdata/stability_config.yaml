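n_participants: 400
seed: 11
waves:
- T0
- T1
- T2
- T3
variables:
- name: intervention
  timeslot: static
  kind: discrete
  role: intervention
  levels:
  - control
  - intervention
- name: selfeff@T1
  timeslot: T1
  kind: continuous
  role: determinant
- name: intention@T2
  timeslot: T2
  kind: continuous
  role: determinant
- name: pa@T2
  timeslot: T2
  kind: continuous
  role: outcome
- name: pa@T3
  timeslot: T3
  kind: continuous
  role: outcome
network:
  arcs:
  - - intervention
    - selfeff@T1
  - - selfeff@T1
    - intention@T2
  - - intention@T2
    - pa@T2
  - - pa@T2
    - pa@T3
  coef:
  - from: intervention
    to: selfeff@T1
    value: 0.9
  - from: selfeff@T1
    to: intention@T2
    value: 0.8
  - from: intention@T2
    to: pa@T2
    value: 0.8
  - from: pa@T2
    to: pa@T3
    value: 0.8
  intercept:
    selfeff@T1: 0.0
    intention@T2: 0.0
    pa@T2: 0.0
    pa@T3: 0.0
  sigma:
    selfeff@T1: 1.0
    intention@T2: 0.6
    pa@T2: 0.6
    pa@T3: 0.6
  cpt:
    intervention:
    - - 0.5
      - 0.5
  config_intercept: []
  config_sigma: []
  trunc: []
concepts: ~
moderator_effects: []
missing_item_rate: 0.0
item_noise_sd: 0.5
missing_cell_rate: 0.1
missing_wave_pattern: []
study_mix: ~
study_var: ~
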