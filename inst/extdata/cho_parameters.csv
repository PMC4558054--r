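"name","value","magnitude_exponent","lower_bound","upper_bound","sensitive_flag"
"VmaxHK",0.000202020202020202,-4,0,Inf,1
"VfmaxPGI",0.000387,-4,0,Inf,1
"VrmaxPGI",5e-05,-5,0,Inf,0
"VmaxPFK",0.000362157842157842,-4,0,Inf,0
"VmaxPGK",0.00135,-3,0,Inf,1
"VmaxPK",0.000591517857142857,-4,0,Inf,1
"VmaxLDH",0.000380244755244755,-4,0,Inf,0
"VmaxrLDH",4.59e-05,-5,0,Inf,0
"VmaxG6PDH",1.694e-05,-5,0,Inf,0
"VmaxPDH",7.6032e-05,-5,0,Inf,0
"VmaxPC",7.2e-06,-6,0,Inf,0
"VmaxIDH",2.16e-05,-5,0,Inf,0
"VmaxAKGDH",0.000132,-4,0,Inf,0
"VmaxMLD",3.92e-05,-5,0,Inf,0
"VmaxME",0.000205333333333333,-4,0,Inf,0
"VfmaxGlnT",4e-05,-5,0,Inf,1
"VrmaxGlnT",7e-06,-6,0,Inf,0
"VfmaxGLDH",3.6e-06,-6,0,Inf,0
"VrmaxGLDH",7.8e-06,-6,0,Inf,0
"VmaxASTA",1.17e-05,-5,0,Inf,0
"VmaxAlaTA",0.0001875,-4,0,Inf,0
"VmaxrAlaTA",0.0001287,-4,0,Inf,0
"VmaxSDHH",4.22222222222222e-06,-6,0,Inf,0
"VmaxASN",5.5e-06,-6,0,Inf,0
"VmaxAAtoSUC",1.28162746344565e-05,-5,0,Inf,0
"VmaxHISARGTA",2.17142857142857e-06,-6,0,Inf,0
"VfmaxGluT",6e-06,-6,0,Inf,0
"VrmaxGluT",3e-06,-6,0,Inf,0
"Vmaxresp",0.00015,-4,0,Inf,1
"Vmaxleak",9e-05,-5,0,Inf,1
"VmaxATPase",0.00081,-4,0,Inf,1
"VfmaxAK",2.5e-05,-5,0,Inf,1
"VrmaxAK",5e-05,-5,0,Inf,1
"Vmaxgrowth",0.22459392545773,-1,0,Inf,1
"VmaxmAb",0.000584911925901742,-4,0,Inf,0
"KmGLC_HK",2,0,0,Inf,0
"KmATP_ADP",1,0,0,Inf,0
"KdG6P",1.5e-07,-7,0,Inf,1
"KaAMP_ATP",0.09,-2,0,Inf,1
"alphaAMP_ATP",0.4,-1,0,Inf,1
"betaAMP_ATP",2.5,0,0,Inf,1
"KmG6P",2.9e-08,-8,0,Inf,1
"KdPEP_PGI",2e-08,-8,0,Inf,0
"KmF6P_rPGI",6e-08,-8,0,Inf,0
"KmF6P_PFK",4e-08,-8,0,Inf,0
"KdCIT_PFK",3e-07,-7,0,Inf,0
"KdLAC_PFK",14,1,0,Inf,0
"KmGAP_PGK",3e-08,-8,0,Inf,0
"KmNAD_PGK",2,0,0,Inf,0
"KmADP_ATP",0.05,-2,0,Inf,1
"KmPEP_PK",1.5e-08,-8,0,Inf,0
"KaF6P_PK",5e-08,-8,0,Inf,0
"alphaF6P_PK",0.5,-1,0,Inf,0
"betaF6P_PK",2,0,0,Inf,0
"KdALA_PK",7,0,0,Inf,0
"KmPYR_LDH",1.5e-07,-7,0,Inf,0
"KmNADH_LDH",0.05,-2,0,Inf,0
"KmLAC_rLDH",12,1,0,Inf,0
"KmNAD_rLDH",2,0,0,Inf,0
"KdPYR_rLDH",8e-08,-8,0,Inf,0
"KmG6P_G6PDH",1.2e-07,-7,0,Inf,0
"KmNADP_G6PDH",0.3,-1,0,Inf,0
"KmPYR_PDH",1.2e-07,-7,0,Inf,0
"KmOAA_PDH",8e-09,-9,0,Inf,0
"KmNAD_PDH",2,0,0,Inf,0
"KmPYR_PC",2e-07,-7,0,Inf,0
"KmCIT_IDH",2.5e-07,-7,0,Inf,0
"KmNAD_IDH",2,0,0,Inf,0
"KmAKG_AKGDH",6e-08,-8,0,Inf,0
"KmNAD_AKGDH",2,0,0,Inf,0
"KmMAL_MLD",2e-07,-7,0,Inf,0
"KmNAD_MLD",2,0,0,Inf,0
"KmMAL_ME",2e-07,-7,0,Inf,0
"KmNADP_ME",0.3,-1,0,Inf,0
"KmGLN_GlnT",1,0,0,Inf,0
"KmGLU_rGlnT",3e-06,-6,0,Inf,0
"KmNH4_rGlnT",2,0,0,Inf,0
"KmGLU_GLDH",4e-06,-6,0,Inf,0
"KmNAD_GLDH",2,0,0,Inf,0
"KmAKG_rGLDH",8e-08,-8,0,Inf,0
"KmNH4_rGLDH",3,0,0,Inf,0
"KmNADH_rGLDH",0.1,-1,0,Inf,0
"KmASP_ASTA",0.5,-1,0,Inf,0
"KmAKG_ASTA",8e-08,-8,0,Inf,0
"KmPYR_AlaTA",1.5e-07,-7,0,Inf,0
"KmGLU_AlaTA",3e-06,-6,0,Inf,0
"KmALA_rAlaTA",1,0,0,Inf,0
"KmAKG_rAlaTA",8e-08,-8,0,Inf,0
"KdGLN_rAlaTA",0.3,-1,0,Inf,0
"KmSER_SDHH",1,0,0,Inf,0
"KmASN_ASN",1,0,0,Inf,0
"KmILE_AAtoSUC",0.5,-1,0,Inf,0
"KmVAL_AAtoSUC",0.5,-1,0,Inf,0
"KmTHR_AAtoSUC",0.5,-1,0,Inf,0
"KmLYS_AAtoSUC",0.5,-1,0,Inf,0
"KmMET_AAtoSUC",0.3,-1,0,Inf,0
"KmHIS_HISARGTA",0.3,-1,0,Inf,0
"KmARG_HISARGTA",0.5,-1,0,Inf,0
"KmGLU_GluT",4e-06,-6,0,Inf,0
"KmGLU_rGluT",1,0,0,Inf,0
"KmNADH",0.05,-2,0,Inf,1
"KmNADH_leak",0.2,-1,0,Inf,0
"KmATP",4,0,0,Inf,1
"KmAMP_rAK",0.15,-1,0,Inf,0
"KdLACgrowth",100,2,0,Inf,0
"KdNH4growth",5,0,0,Inf,1
"KmG6Pgrowth",2e-08,-8,0,Inf,0
"KmCITgrowth",4e-08,-8,0,Inf,0
"KmR5Pgrowth",5e-09,-9,0,Inf,0
"KmATPgrowth",0.5,-1,0,Inf,0
"KmNADPHgrowth",0.4,-1,0,Inf,0
"KmATPmAb",0.5,-1,0,Inf,0
"KmALAgrowth",0.03,-2,0,Inf,0
"KmARGgrowth",0.05,-2,0,Inf,0
"KmASPgrowth",0.04,-2,0,Inf,0
"KmASNgrowth",0.05,-2,0,Inf,0
"KmGLNgrowth",0.06,-2,0,Inf,0
"KmGLUgrowth",0.05,-2,0,Inf,0
"KmGLYgrowth",0.03,-2,0,Inf,0
"KmHISgrowth",0.02,-2,0,Inf,0
"KmILEgrowth",0.06,-2,0,Inf,0
"KmLYSgrowth",0.05,-2,0,Inf,0
"KmMETgrowth",0.02,-2,0,Inf,0
"KmPHEgrowth",0.03,-2,0,Inf,0
"KmSERgrowth",0.04,-2,0,Inf,0
"KmTHRgrowth",0.04,-2,0,Inf,0
"KmTYRgrowth",0.03,-2,0,Inf,0
"KmVALgrowth",0.05,-2,0,Inf,0
"KmALAmAb",0.04,-2,0,Inf,0
"KmARGmAb",0.06,-2,0,Inf,0
"KmASPmAb",0.05,-2,0,Inf,0
"KmASNmAb",0.06,-2,0,Inf,0
"KmGLNmAb",0.08,-2,0,Inf,0
"KmGLUmAb",0.06,-2,0,Inf,0
"KmGLYmAb",0.04,-2,0,Inf,0
"KmHISmAb",0.03,-2,0,Inf,0
"KmILEmAb",0.07,-2,0,Inf,0
"KmLYSmAb",0.06,-2,0,Inf,0
"KmMETmAb",0.03,-2,0,Inf,0
"KmPHEmAb",0.04,-2,0,Inf,0
"KmSERmAb",0.05,-2,0,Inf,0
"KmTHRmAb",0.05,-2,0,Inf,0
"KmTYRmAb",0.04,-2,0,Inf,0
"KmVALmAb",0.06,-2,0,Inf,0
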