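name: powercho_fedbatch
medium: PowerCHO-2
mode: fed-batch
duration: 360.0
sampling_interval: 24.0
initial:
  Xv: 0.2
  V: 1.0
  mAb: 0.0
  GLC: 40.0
  GLN: 6.5
  LAC: 0.1
  NH4: 0.18
  ALA: 0.45
  ASP: 1.1
  ASN: 3.2
  SER: 2.4
  GLY: 0.8
  HIS: 0.7
  ARG: 2.4
  ILE: 2.6
  VAL: 1.5
  THR: 1.4
  LYS: 1.7
  MET: 0.6
  PHE: 0.8
  TYR: 0.7
  GLU: 0.7
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
feed:
  composition:
    GLC: 100.0
    GLN: 16.0
    ALA: 1.125
    ASP: 2.75
    ASN: 8.0
    SER: 6.0
    GLY: 2.0
    HIS: 1.75
    ARG: 6.0
    ILE: 6.5
    VAL: 3.75
    THR: 3.5
    LYS: 4.25
    MET: 1.5
    PHE: 2.0
    TYR: 1.75
    GLU: 1.75
  policy:
    interval: 24.0
    start: 24.0
    glucose_floor: 10.0
    set_point: 40.0
    conditional: no
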