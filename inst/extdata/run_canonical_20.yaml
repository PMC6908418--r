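forcing:
  photoperiod: 12L:12D
  irradiance: 150
  irradiance_shape: square
  o2_percent: 20
  temperature_C: 28
  salinity: 35
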