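name: toy_batch
medium: toy
mode: batch
duration: 72.0
sampling_interval: 6.0
initial:
  S: 20.0
  Q: 0.0
  P: 1.0e-07
  Xv: 1.0
  V: 1.0
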