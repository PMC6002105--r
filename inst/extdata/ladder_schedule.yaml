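segments:
- duration_ns: 32.0
  temperature_K: 303.0
- duration_ns: 12.0
  temperature_K: 333.0
- duration_ns: 12.0
  temperature_K: 363.0
- duration_ns: 20.0
  temperature_K: 390.0
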