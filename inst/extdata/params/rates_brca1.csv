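transition,age_lo,age_hi,rate,se,lo,hi
bc_death,0,49,0.0209,0.002,,
bc_death,50,69,0.0318,0.002,,
bc_death,70,,0.1066,0.005,,
mbc_death,0,49,0.2033,0.034,,
mbc_death,50,69,0.2558,0.048,,
mbc_death,70,,0.2608,0.029,,
oc_death,15,44,0.0621,0.006,,
oc_death,45,54,0.1086,0.007,,
oc_death,55,64,0.1536,0.007,,
oc_death,65,74,0.1983,0.008,,
oc_death,75,,0.2741,0.012,,
df_bc,21,30,0.0059,0.002,,
df_bc,31,40,0.0248,0.003,,
df_bc,41,50,0.0309,0.004,,
df_bc,51,60,0.0269,0.007,,
df_bc,61,,0.0167,0.005,,
df_oc,30,39,0.0016,0.0007,,
df_oc,40,49,0.0155,0.0011,,
df_oc,50,59,0.0220,0.0013,,
df_oc,60,69,0.0165,0.0015,,
df_oc,70,,0.0079,0.0011,,
bc_cbc,21,30,0.0119,0.007,,
bc_cbc,31,40,0.0407,0.007,,
bc_cbc,41,50,0.0209,0.005,,
bc_cbc,51,60,0.0328,0.007,,
bc_cbc,61,70,0.0117,0.007,,
bc_cbc,71,,0.0197,0.014,,
bc_mbc,0,,0.0278,0.002,,
bc_oc,0,,0.0185,,0.012,0.058
postoc_bc,0,,0.0144,,0.01,0.043
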