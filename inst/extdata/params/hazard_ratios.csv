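effect,strategy,mutation,hr,se
oc_incidence,PBSO,,0.28,0.14
oc_incidence_prior_bc,PBSO,,0.14,0.14
bc_incidence,PBM,,0.09,0.09
erpos_bc_incidence,CP,,0.31,0.06
cbc_incidence,CP,BRCA1,0.44,0.15
cbc_incidence,CP,BRCA2,0.33,0.12
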