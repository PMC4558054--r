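sums:
  ammonia_production:
    V_GLDH: 1.0
    V_GlnT: 1.0
    V_SDHH: 1.0
    V_ASN: 1.0
    V_HISARGTA: 1.0
  tca_influx:
    V_GLDH: 1.0
    V_PDH: 1.0
    V_AlaTA: 1.0
    V_PC: 1.0
    V_AAtoSUC: 5.0
  net_atp_production:
    V_PGK: 1.0
    V_PK: 1.0
    V_AKGDH: 1.0
    V_PC: 1.0
    V_GlnT: 1.0
    V_resp: 5.0
  aa_to_tca:
    V_GLDH: 1.0
    V_AlaTA: 1.0
    V_AAtoSUC: 5.0
  glycolytic_atp:
    V_HK: 1.0
    V_PFK: 1.0
  respiratory_atp:
    V_resp: 5.0
ratios:
  aa_contribution_tca:
    num: aa_to_tca
    den: tca_influx
  pdh_contribution_tca:
    num: V_PDH
    den: tca_influx
  pc_contribution_tca:
    num: V_PC
    den: tca_influx
  atp_from_glycolysis:
    num: glycolytic_atp
    den: net_atp_production
  atp_from_respiration:
    num: respiratory_atp
    den: net_atp_production
  pdh_to_pk:
    num: V_PDH
    den: V_PK
  ldh_to_pk:
    num: V_LDH
    den: V_PK
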