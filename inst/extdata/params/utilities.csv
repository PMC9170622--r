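kind,key,age_lo,age_hi,value,var_pct
df_age,DF,30,39,0.901,
df_age,DF,40,49,0.871,
df_age,DF,50,59,0.842,
df_age,DF,60,69,0.823,
df_age,DF,70,79,0.790,
df_age,DF,80,,0.736,
state,BC,,,0.637,20
state,MBC,,,0.533,20
state,OC,,,0.410,20
strategy,IS,,,0.960,5
strategy,PBM,,,0.880,10
strategy,PBSO,,,0.900,10
strategy,PBM_PBSO,,,0.790,10
strategy,CP,,,0.900,5
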