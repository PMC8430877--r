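# triplicate 2-h deployment, 10 mL isopropyl alcohol extraction
replicate_id,deployment_h,Ci_g_per_L,Cf_g_per_L,VE_L
r1,2,0.100,0.09395,0.01
r2,2,0.100,0.09410,0.01
r3,2,0.100,0.09382,0.01
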