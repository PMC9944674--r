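# Ocular and systemic physiology: adult human.
# Units are stated per key; loaders convert to internal units
# (volumes mL, time h) on ingestion.
species_id: human
ocular:
  tear_volume_uL:
    value: 7
    provenance: "physiological tear volume of the human eye (~7 uL)"
  precornea_max_volume_uL:
    value: 37
    provenance: "conjunctival sac capacity: physiological tear volume (7 uL) plus a typical 30 uL instilled drop; excess is spilled"
  drainage_rate_constant_per_min:
    value: 1
    provenance: "nasolacrimal drainage rate constant for aqueous (water-like viscosity) solutions; species-independent default"
  aqueous_turnover_uL_per_min:
    value: 2.5
    provenance: "human aqueous humor formation rate, fluorophotometry literature (2.4-3.0 uL/min)"
  compartment_volumes_mL:
    cornea_epi:
      value: 0.0065
      provenance: "corneal epithelium ~50 um over ~1.3 cm2"
    cornea_stroma:
      value: 0.062
      provenance: "corneal stroma+endothelium ~0.48 mm over ~1.3 cm2"
    conjunctiva:
      value: 0.30
      provenance: "bulbar+palpebral conjunctival tissue, anatomy literature"
    AH:
      value: 0.26
      provenance: "human anterior+posterior chamber aqueous volume ~260 uL"
    ICB:
      value: 0.16
      provenance: "iris (~60 mg) plus ciliary body (~100 mg)"
    sclera:
      value: 0.70
      provenance: "human scleral shell wet weight"
    choroid:
      value: 0.18
      provenance: "human choroid wet weight"
    retina:
      value: 0.20
      provenance: "human neural retina wet weight"
    VH:
      value: 4.0
      provenance: "human vitreous humor volume ~4 mL"
  exchange_surfaces_cm2:
    precornea.cornea_epi:
      value: 1.3
      provenance: "anterior corneal surface area, human"
    precornea.conjunctiva:
      value: 17
      provenance: "human conjunctival sac surface area (~16-18 cm2)"
    cornea_epi.cornea_stroma:
      value: 1.3
      provenance: "epithelium-stroma interface = corneal area"
    cornea_stroma.AH:
      value: 1.3
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
      value: 6
      provenance: "posterior segment inner scleral surface, human globe"
    choroid.retina:
      value: 6
      provenance: "choroid-RPE-retina interface, human posterior segment"
    retina.VH:
      value: 6
      provenance: "inner limiting membrane surface, human"
  pigmented:
    ICB: true
    retina: true
    choroid: true
    sclera: true
systemic:
  body_weight_kg:
    value: 70
    provenance: "reference adult"
  hematocrit:
    value: 0.40
    provenance: "reference adult hematocrit"
  cardiac_output_mL_per_min:
    value: 5600
    provenance: "reference adult cardiac output 5.6 L/min"
  tissues:
    lung:
      volume_mL: 530
      flow_mL_per_min: 5600
      provenance: "lung receives total cardiac output; volume from reference-man tables"
    liver:
      volume_mL: 1690
      flow_mL_per_min: 1450
      provenance: "total hepatic blood flow (arterial+portal), reference-man tables"
    kidney:
      volume_mL: 280
      flow_mL_per_min: 1100
      provenance: "renal blood flow, reference-man tables"
    muscle:
      volume_mL: 29000
      flow_mL_per_min: 750
      provenance: "skeletal muscle ~40% BW"
    adipose:
      volume_mL: 14500
      flow_mL_per_min: 260
      provenance: "adipose tissue, reference-man tables"
    skin:
      volume_mL: 3300
      flow_mL_per_min: 300
      provenance: "skin, reference-man tables"
    brain:
      volume_mL: 1450
      flow_mL_per_min: 700
      provenance: "brain, reference-man tables"
    heart:
      volume_mL: 310
      flow_mL_per_min: 240
      provenance: "heart, reference-man tables"
    rest:
      volume_mL: 9000
      flow_mL_per_min: 800
      provenance: "carcass remainder incl. gut wall and bone; closes flow balance at cardiac output"
  blood:
    venous_volume_mL:
      value: 3400
      provenance: "2/3 of ~5.1 L blood volume"
    arterial_volume_mL:
      value: 1700
      provenance: "1/3 of blood volume"
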