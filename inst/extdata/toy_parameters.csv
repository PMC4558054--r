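"name","value","magnitude_exponent","lower_bound","upper_bound","sensitive_flag"
"Vmax_upt",2e-04,-4,0,Inf,1
"KmS_upt",1,0,0,Inf,1
"Vmax_conv",3e-04,-4,0,Inf,1
"KmP_conv",1e-07,-7,0,Inf,0
"KdQ_conv",20,1,0,Inf,0
"Vmax_deg",5e-05,-5,0,Inf,0
"KmP_deg",2e-07,-7,0,Inf,0
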