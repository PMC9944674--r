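# Ocular and systemic physiology: albino New Zealand White rabbit.
# Units are stated per key; loaders convert to internal units
# (volumes mL, time h) on ingestion.
species_id: NZ_rabbit
ocular:
  tear_volume_uL:
    value: 5
    provenance: "physiological tear volume of the rabbit eye; standard precorneal fluid value"
  precornea_max_volume_uL:
    value: 35
    provenance: "conjunctival sac capacity: physiological tear volume (5 uL) plus a typical 30 uL instilled drop; excess is spilled"
  drainage_rate_constant_per_min:
    value: 1
    provenance: "nasolacrimal drainage rate constant for aqueous (water-like viscosity) solutions"
  aqueous_turnover_uL_per_min:
    value: 3.0
    provenance: "rabbit aqueous humor formation/outflow rate, tonography literature (2.5-3.5 uL/min)"
  compartment_volumes_mL:
    cornea_epi:
      value: 0.006
      provenance: "corneal epithelium ~40 um over ~1.5 cm2, anatomy literature"
    cornea_stroma:
      value: 0.055
      provenance: "corneal stroma+endothelium, ~0.35 mm over ~1.5 cm2"
    conjunctiva:
      value: 0.25
      provenance: "bulbar+palpebral conjunctival tissue mass ~0.25 g, density 1 g/mL"
    AH:
      value: 0.25
      provenance: "rabbit anterior+posterior chamber aqueous humor volume ~250 uL"
    ICB:
      value: 0.06
      provenance: "iris plus ciliary body wet weight ~60 mg"
    sclera:
      value: 0.45
      provenance: "scleral shell wet weight ~0.45 g"
    choroid:
      value: 0.05
      provenance: "choroid wet weight ~50 mg"
    retina:
      value: 0.09
      provenance: "neural retina wet weight ~90 mg"
    VH:
      value: 1.4
      provenance: "rabbit vitreous humor volume ~1.4 mL"
  exchange_surfaces_cm2:
    precornea.cornea_epi:
      value: 1.5
      provenance: "anterior corneal surface area, rabbit"
    precornea.conjunctiva:
      value: 18
      provenance: "bulbar+palpebral conjunctival sac surface, rabbit (Watsky-type estimates ~15-20 cm2)"
    cornea_epi.cornea_stroma:
      value: 1.5
      provenance: "epithelium-stroma interface = corneal area"
    cornea_stroma.AH:
      value: 1.5
      provenance: "corneal endothelial surface = corneal area"
    AH.ICB:
      value: 6
      provenance: "iris anterior surface plus folded ciliary processes in contact with aqueous"
    ICB.VH:
      value: 3
      provenance: "posterior ciliary body / zonular interface with vitreous"
    conjunctiva.sclera:
      value: 16
      provenance: "episcleral contact under bulbar conjunctiva"
    sclera.choroid:
      value: 4.5
      provenance: "posterior segment inner scleral surface"
    choroid.retina:
      value: 4.5
      provenance: "choroid-RPE-retina interface, posterior segment"
    retina.VH:
      value: 4.5
      provenance: "inner limiting membrane surface"
  pigmented:
    ICB: false
    retina: false
    choroid: false
    sclera: false
systemic:
  body_weight_kg:
    value: 2.5
    provenance: "typical adult NZW rabbit"
  hematocrit:
    value: 0.36
    provenance: "rabbit hematocrit, clinical chemistry reference"
  cardiac_output_mL_per_min:
    value: 480
    provenance: "rabbit cardiac output ~190 mL/min/kg, reference physiological parameter compilations"
  tissues:
    lung:
      volume_mL: 17
      flow_mL_per_min: 480
      provenance: "lung receives total cardiac output; volume from organ-weight tables"
    liver:
      volume_mL: 100
      flow_mL_per_min: 85
      provenance: "total hepatic blood flow (arterial+portal), reference compilations"
    kidney:
      volume_mL: 15
      flow_mL_per_min: 70
      provenance: "renal blood flow, reference compilations"
    muscle:
      volume_mL: 1350
      flow_mL_per_min: 80
      provenance: "skeletal muscle ~54% BW"
    adipose:
      volume_mL: 120
      flow_mL_per_min: 15
      provenance: "adipose ~5% BW"
    skin:
      volume_mL: 110
      flow_mL_per_min: 24
      provenance: "skin organ-weight tables"
    brain:
      volume_mL: 10
      flow_mL_per_min: 10
      provenance: "brain organ-weight tables"
    heart:
      volume_mL: 6
      flow_mL_per_min: 16
      provenance: "heart organ-weight tables"
    rest:
      volume_mL: 300
      flow_mL_per_min: 175
      provenance: "carcass remainder incl. gut wall and bone; closes flow balance below cardiac output"
  blood:
    venous_volume_mL:
      value: 90
      provenance: "2/3 of ~135 mL rabbit blood volume"
    arterial_volume_mL:
      value: 45
      provenance: "1/3 of rabbit blood volume"
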