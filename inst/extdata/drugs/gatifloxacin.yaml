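# Drug-specific parameter record: gatifloxacin ophthalmic solution.
# Same conventions as levofloxacin.yaml.
api_id: gatifloxacin
physicochemistry:
  mwt_g_mol: {value: 375.4, source: predicted}
  logp_neutral: {value: -0.8, source: literature}
  fu_plasma_pct: {value: 80, source: literature}
  fu_melanin_pct: {value: 0.4, source: fitted}
  rbp: {rabbit: 0.9, human: 0.9, source: fitted}
  solubility_mg_mL: {value: 60, ph: 4, source: literature}
  pkas:
    - {value: 1.04, type: base}
    - {value: 5.92, type: acid}
    - {value: 9.1, type: base}
absorption_clearance:
  peff_1e-4_cm_s: {rabbit: 2, human: 2, source: fitted}
  renal_fraction: {rabbit: 0.12, human: 0.12, source: fitted}
  clint_L_h: {rabbit: 0.16, human: 2.7, source: fitted}
ocular:
  permeability_cm_s:
    cornea_epi: {value: 3.0e-7, source: fitted}
    cornea_stroma: {value: 7.78e-5, source: default}
    conjunctiva: {value: 4.35e-7, source: default}
    AH: {value: 8.76e-6, source: default}
    ICB: {value: 8.94e-5, source: default}
    sclera: {value: 4.28e-6, source: default}
    choroid: {value: 7.68e-4, source: default}
    retina: {value: 2.0e-6, source: default}
    VH: {value: 6.9e-6, source: default}
  systemic_absorption_rate_per_s:
    choroid: {value: 1.15e-4, source: default}
    retina: {value: 1.39e-4, source: default}
    conjunctiva: {value: 3.77e-4, source: default}
    ICB: {value: 7.0e-4, source: fitted}
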