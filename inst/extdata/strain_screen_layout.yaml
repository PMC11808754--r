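scan_length_um: 50000.0
spots:
- label: A1
  center_um: 1500.0
  width_um: 3000.0
  role: sample
- label: A2
  center_um: 6722.2222222
  width_um: 3000.0
  role: sample
- label: A3
  center_um: 11944.4444444
  width_um: 3000.0
  role: sample
- label: B1
  center_um: 17166.6666667
  width_um: 3000.0
  role: sample
- label: B2
  center_um: 22388.8888889
  width_um: 3000.0
  role: sample
- label: B3
  center_um: 27611.1111111
  width_um: 3000.0
  role: sample
- label: C1
  center_um: 32833.3333333
  width_um: 3000.0
  role: sample
- label: C2
  center_um: 38055.5555556
  width_um: 3000.0
  role: sample
- label: C3
  center_um: 43277.7777778
  width_um: 3000.0
  role: sample
- label: MB
  center_um: 48500.0
  width_um: 3000.0
  role: media_blank
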