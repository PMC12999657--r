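# N-desmethyldoxepin (nordoxepin) compound parameterisation.
# The metabolite is formed systemically (never dosed orally), so its
# solubility is carried but never rate-limiting. total_hepatic_clearance is
# the intrinsic clearance (L/min) referenced to unbound liver water
# concentration that lumps the non-CYP2D6 elimination routes.
name: nordoxepin
molecular_weight: 265.35
log_p: 3.60
pka: 10.47
is_base: true
fraction_unbound: 0.21
solubility_mg_L: 0.00361
solubility_ph: 7.0
intestinal_permeability_cm_min: 7.87e-4
organ_permeability_cm_min: 0.33
blood_plasma_ratio: 1.0
partition_method: schmitt
total_hepatic_clearance_L_min: 2.50
pathways:
  CYP2D6:
    km_uM: 40
    kcat_per_min: 160
    reference_concentration_uM: 0.40
    product: inactive
cyp2d6_kcat_by_phenotype:
  non_genotyped: 160
  UM: 505
  NM: 165
  IM: 30
  PM: 0
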