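# Declarative strategy specifications. Each entry binds hazard-ratio effects
# (keys into hazard_ratios.csv), a disutility mode, one-off intervention cost
# keys, a surveillance/follow-up profile, and the recurring-cost flags.
IS:
  hr_effects: []
  disutility_mode: surveillance
  one_off: []
  surveillance: is_full
  hrt: false
  implant_lumps: false
  cp_drug: false
CP:
  hr_effects: [erpos_bc_incidence, cbc_incidence]
  disutility_mode: five_year
  one_off: []
  surveillance: is_full
  hrt: false
  implant_lumps: false
  cp_drug: true
PBM:
  hr_effects: [bc_incidence]
  disutility_mode: surgical
  one_off: [pbm_surgery, reconstruction, reshaping]
  surveillance: consults_semiannual
  hrt: false
  implant_lumps: true
  cp_drug: false
PBSO:
  hr_effects: [oc_incidence, oc_incidence_prior_bc]
  disutility_mode: surgical
  one_off: [pbso_surgery]
  surveillance: is_full
  hrt: true
  implant_lumps: false
  cp_drug: false
PBM_PBSO:
  hr_effects: [bc_incidence, oc_incidence, oc_incidence_prior_bc]
  disutility_mode: surgical
  one_off: [pbm_surgery, reconstruction, reshaping, pbso_surgery]
  surveillance: consults_annual
  hrt: true
  implant_lumps: true
  cp_drug: false
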