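n_points: 80
roles:
  TEARDROP_CAUDAL: 0
  ACETAB_LATERAL_EDGE: 11
  SOURCIL_MEDIAL: 4
  SOURCIL_LATERAL: 8
  FEMORAL_HEAD_APEX: 26
  HEAD_CONTOUR:
  - 12
  - 41
  HEADNECK_SUPERIOR_CONTOUR:
  - 42
  - 51
  NECK_MEDIAL:
  - 60
  - 67
  NECK_LATERAL:
  - 52
  - 59
  SHAFT_MEDIAL:
  - 74
  - 79
  SHAFT_LATERAL:
  - 68
  - 73
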