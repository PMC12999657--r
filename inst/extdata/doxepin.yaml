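# Doxepin compound parameterisation (model input values).
# Units: molecular_weight g/mol; solubility mg/L at the stated pH;
# permeabilities cm/min; km and reference_concentration umol/L; kcat 1/min.
name: doxepin
molecular_weight: 279.37
log_p: 3.70
pka: 9.76
is_base: true
fraction_unbound: 0.20
solubility_mg_L: 31.60
solubility_ph: 7.0
intestinal_permeability_cm_min: 7.86e-4
organ_permeability_cm_min: 0.30
blood_plasma_ratio: 1.0
partition_method: rodgers_rowland
pathways:
  CYP2C19:
    km_uM: 5
    kcat_per_min: 28
    reference_concentration_uM: 0.76
    product: metabolite
  CYP2D6:
    km_uM: 88
    kcat_per_min: 260
    reference_concentration_uM: 0.40
    product: inactive
# CYP2D6 turnover by phenotype; Km is held constant across phenotypes.
cyp2d6_kcat_by_phenotype:
  non_genotyped: 260
  UM: 505
  NM: 299
  IM: 85
  PM: 0
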