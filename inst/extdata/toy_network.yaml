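name: toy-uptake-chain
description: 'Three-reaction toy model: substrate uptake into a per-cell intermediate,
  conversion to a secreted product with product inhibition, and first-order like degradation.
  Used for fast calibration / recovery oracles.'
biomass: ~
metabolites:
- id: S
  compartment: extracellular
- id: Q
  compartment: extracellular
- id: P
  compartment: intracellular
- id: Xv
  compartment: cells
- id: V
  compartment: volume
reactions:
- id: V_upt
  stoichiometry:
    S: -1.0
    P: 1.0
  rate_law:
    Vmax: Vmax_upt
    substrates:
    - species: S
      Km: KmS_upt
    regulation: []
  reversible_pair: ~
  reconstructed: no
- id: V_conv
  stoichiometry:
    P: -1.0
    Q: 1.0
  rate_law:
    Vmax: Vmax_conv
    substrates:
    - species: P
      Km: KmP_conv
    regulation:
    - kind: noncompetitive_inhibition
      effector: Q
      K: KdQ_conv
  reversible_pair: ~
  reconstructed: no
- id: V_deg
  stoichiometry:
    P: -1.0
  rate_law:
    Vmax: Vmax_deg
    substrates:
    - species: P
      Km: KmP_deg
    regulation: []
  reversible_pair: ~
  reconstructed: no
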