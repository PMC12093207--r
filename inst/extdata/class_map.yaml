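classes:
  gel: 0
  bubble: 1
  HbA1c_A0: 2
  MetHb: 3
  HbF: 4
  HbA2: 5
  pI_marker: 6
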