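name: biogro_batch
medium: Biogro-CHO
mode: batch
duration: 144.0
sampling_interval: 12.0
initial:
  Xv: 0.2
  V: 1.0
  mAb: 0.0
  GLC: 25.0
  GLN: 4.0
  LAC: 0.1
  NH4: 0.22
  ALA: 0.35
  ASP: 0.35
  ASN: 1.2
  SER: 0.9
  GLY: 0.7
  HIS: 0.5
  ARG: 1.4
  ILE: 1.6
  VAL: 1.1
  THR: 1.1
  LYS: 1.3
  MET: 0.45
  PHE: 0.6
  TYR: 0.55
  GLU: 0.5
  G6P: 1.0e-07
  F6P: 4.0e-08
  GAP: 2.0e-08
  PEP: 1.0e-08
  PYR: 1.0e-07
  CIT: 2.0e-07
  AKG: 5.0e-08
  MAL: 1.5e-07
  OAA: 1.0e-08
  R5P: 2.0e-08
  GLUin: 2.0e-06
  ATP: 3.0e-06
  ADP: 6.0e-07
  AMP: 3.0e-07
  NAD: 2.0e-06
  NADH: 2.0e-07
  NADP: 5.0e-08
  NADPH: 2.0e-07
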