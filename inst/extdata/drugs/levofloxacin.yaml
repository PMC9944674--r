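# Drug-specific parameter record: levofloxacin ophthalmic solution.
# Percent fields are percents here and converted to fractions on load;
# permeabilities in cm/s, systemic absorption rates in 1/s, CLint in L/h.
# Per-species keys (rabbit/human) where values differ between species.
api_id: levofloxacin
physicochemistry:
  mwt_g_mol: {value: 361.4, source: predicted}
  logp_neutral: {value: -0.4, source: literature}
  fu_plasma_pct: {value: 75, source: literature}
  fu_melanin_pct: {value: 0.1, source: fitted}
  rbp: {rabbit: 0.95, human: 0.84, source: fitted}
  solubility_mg_mL: {value: 50, ph: 6.9, source: literature}
  pkas:
    - {value: 5.73, type: acid}
    - {value: 6.8, type: base}
    - {value: 8.08, type: base}
absorption_clearance:
  peff_1e-4_cm_s: {rabbit: 3.97, human: 3.97, source: predicted}
  renal_fraction: {rabbit: 0.1, human: 0.09, source: fitted}
  clint_L_h: {rabbit: 0.054, human: 2, source: fitted}
ocular:
  permeability_cm_s:
    cornea_epi: {value: 1.85e-7, source: fitted}
    cornea_stroma: {value: 1.04e-5, source: default}
    conjunctiva: {value: 2.5e-7, source: fitted}
    AH: {value: 9.14e-6, source: default}
    ICB: {value: 8.98e-5, source: default}
    sclera: {value: 5.71e-6, source: default}
    choroid: {value: 1.02e-4, source: default}
    retina: {value: 2.01e-6, source: default}
    VH: {value: 7.2e-6, source: default}
  systemic_absorption_rate_per_s:
    choroid: {value: 1.53e-4, source: default}
    retina: {value: 1.4e-4, source: default}
    conjunctiva: {value: 3.77e-4, source: default}
    ICB: {value: 1.246e-3, source: fitted}
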