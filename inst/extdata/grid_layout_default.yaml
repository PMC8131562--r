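planar_points:
- - 0.2
  - 2.4
- - 0.6
  - 2.4
- - 1.0
  - 2.4
- - 1.4
  - 2.4
- - 1.8
  - 2.4
- - 2.2
  - 2.4
- - 2.6
  - 2.4
- - 3.0
  - 2.4
- - 3.4
  - 2.4
- - 3.8
  - 2.4
- - 0.2
  - 2.8
- - 0.6
  - 2.8
- - 1.0
  - 2.8
- - 1.4
  - 2.8
- - 1.8
  - 2.8
- - 2.2
  - 2.8
- - 2.6
  - 2.8
- - 3.0
  - 2.8
- - 3.4
  - 2.8
- - 3.8
  - 2.8
- - 0.2
  - 3.2
- - 0.6
  - 3.2
- - 1.0
  - 3.2
- - 1.4
  - 3.2
- - 1.8
  - 3.2
- - 2.2
  - 3.2
- - 2.6
  - 3.2
- - 3.0
  - 3.2
- - 3.4
  - 3.2
- - 3.8
  - 3.2
- - 0.2
  - 3.6
- - 0.6
  - 3.6
- - 1.0
  - 3.6
- - 1.4
  - 3.6
- - 1.8
  - 3.6
- - 2.2
  - 3.6
- - 2.6
  - 3.6
- - 3.0
  - 3.6
- - 3.4
  - 3.6
- - 3.8
  - 3.6
- - 0.2
  - 3.8
- - 0.6
  - 3.8
- - 1.0
  - 3.8
- - 1.4
  - 3.8
- - 1.8
  - 3.8
- - 2.2
  - 3.8
- - 2.6
  - 3.8
- - 3.0
  - 3.8
- - 3.4
  - 3.8
- - 3.8
  - 3.8
- - 0.2
  - 4.0
- - 0.6
  - 4.0
- - 1.0
  - 4.0
- - 1.4
  - 4.0
- - 1.8
  - 4.0
- - 2.2
  - 4.0
- - 2.6
  - 4.0
- - 3.0
  - 4.0
- - 3.4
  - 4.0
- - 3.8
  - 4.0
- - 0.2
  - 4.2
- - 0.6
  - 4.2
- - 1.0
  - 4.2
- - 1.4
  - 4.2
- - 1.8
  - 4.2
- - 2.2
  - 4.2
- - 2.6
  - 4.2
- - 3.0
  - 4.2
- - 3.4
  - 4.2
- - 3.8
  - 4.2
heights:
- 0.72
- 1.19
- 1.56
step_short_m: 0.2
step_long_m: 0.4
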