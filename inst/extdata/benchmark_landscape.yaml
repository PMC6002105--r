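lambda: 10.0
confinement_radius: 54.0
wall_stiffness: 1.0
wells:
- center:
  - 0.0
  - 0.0
  - 0.0
  orientation:
  - 1.0
  - 0.0
  - 0.0
  - 0.0
  depth: 16.8594396
  width: 2.5
  label: native
- center:
  - 0.0
  - 0.0
  - 0.0
  orientation:
  - 1.0
  - 0.0
  - 0.0
  - 0.0
  depth: 7.8275969
  width: 7.0
  label: funnel
- center:
  - 32.0
  - 0.0
  - 0.0
  orientation:
  - 0.4535961
  - 0.0
  - 0.0
  - 0.8912074
  depth: 11.440334
  width: 1.7
  label: trap
- center:
  - -22.0
  - 22.0
  - 7.0
  orientation:
  - 0.6967067
  - -0.5072474
  - -0.5072474
  - -0.0
  depth: 11.440334
  width: 1.7
  label: trap
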