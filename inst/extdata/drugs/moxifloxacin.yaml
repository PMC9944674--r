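# Drug-specific parameter record: moxifloxacin ophthalmic solution.
# Same conventions as levofloxacin.yaml.
api_id: moxifloxacin
physicochemistry:
  mwt_g_mol: {value: 401.44, source: predicted}
  logp_neutral: {value: 0.01, source: literature}
  fu_plasma_pct: {value: 84, source: literature}
  fu_melanin_pct: {value: 1, source: fitted}
  rbp: {rabbit: 0.9, human: 0.9, source: fitted}
  solubility_mg_mL: {value: 17.68, ph: 7.4, source: literature}
  pkas:
    - {value: 1.53, type: base}
    - {value: 6, type: acid}
    - {value: 9.2, type: base}
absorption_clearance:
  peff_1e-4_cm_s: {rabbit: 0.1, human: 4, source: fitted}
  renal_fraction: {rabbit: 0.11, human: 0.02, source: fitted}
  clint_L_h: {rabbit: 3.7, human: 8, source: fitted}
ocular:
  permeability_cm_s:
    cornea_epi: {value: 8.0e-7, source: fitted}
    cornea_stroma: {value: 1.43e-5, source: default}
    conjunctiva: {value: 4.36e-7, source: default}
    AH: {value: 4.0e-5, source: fitted}
    ICB: {value: 6.4e-4, source: default}
    sclera: {value: 7.89e-6, source: default}
    choroid: {value: 1.42e-4, source: default}
    retina: {value: 1.43e-5, source: default}
    VH: {value: 6.7e-6, source: default}
  systemic_absorption_rate_per_s:
    choroid: {value: 2.12e-4, source: default}
    retina: {value: 9.95e-4, source: default}
    conjunctiva: {value: 3.78e-4, source: default}
    ICB: {value: 8.3e-4, source: default}
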