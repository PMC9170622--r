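currency: EUR
watermark: synthetic fixture costs (not tariff-derived)
one_off:
  pbm_surgery: 11000.0
  pbso_surgery: 7500.0
  reconstruction_implant: 9000.0
  reconstruction_autologous: 22000.0
  reshaping: 5000.0
recurring:
  consult_gyn: 130.0
  mammography: 170.0
  mri_breast: 500.0
  vaginal_ultrasound: 110.0
  tamoxifen_year: 250.0
  hrt_year: 400.0
annuity:
  implant_replacement: 8500.0
bc:
  surgery: 13000.0
  radiotherapy: 15000.0
  chemo_tnbc: 36000.0
  chemo_her2: 72000.0
  hormone_year: 900.0
  followup_year: 700.0
oc:
  surgery: 21000.0
  chemo_first_line: 22000.0
  parpi_year: 45000.0
  recurrence_year: 16000.0
  followup_year: 600.0
mbc:
  total_tnbc: 70000.0
  os_tnbc: 1.2
  total_hrpos: 90000.0
  os_hrpos: 2.5
  total_her2: 180000.0
  os_her2: 2.2
palliative:
  lump: 30000.0
assumptions:
  implant_share: 0.95
  reshaping_share: 0.5
  radiotherapy_share: 0.38
  relapse_share: 0.73
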