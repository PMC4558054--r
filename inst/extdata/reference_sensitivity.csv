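"parameter","mean_ee","sd_ee"
"Vmaxgrowth",4.6,6.9
"VmaxPK",1.7,4.1
"VrmaxAK",1.6,3.6
"VmaxPGK",1.4,3.5
"Vmaxresp",1.4,3.6
"VfmaxAK",1.3,2.9
"VmaxHK",1.3,3.3
"VmaxATPase",1.2,4.7
"KmATP",1.1,4
"KmADP_ATP",1.1,2.6
"KmNADH",0.9,3.1
"KdNH4growth",0.9,3.4
"KmG6P",0.9,3.4
"alphaAMP_ATP",0.8,2.5
"VfmaxGlnT",0.7,3.1
"betaAMP_ATP",0.6,2.5
"Vmaxleak",0.6,1.6
"VfmaxPGI",0.6,2.1
"KaAMP_ATP",0.6,1.7
"KdG6P",0.6,1.7
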