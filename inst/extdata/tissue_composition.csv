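# Tissue composition table used by both partition-coefficient methods.
# Provenance: fractional tissue water (extra-/intracellular), neutral lipid
# and neutral phospholipid fractions and acidic phospholipid concentrations
# follow the published Rodgers-Rowland-lineage composition data for adult
# tissues; protein fractions are representative literature values used only
# by the membrane-composition (Schmitt-type) method. The stomach row reuses
# the gut values and the carcass remainder ("rest") row carries generic
# soft-tissue values; neither is tabulated in the original sources.
# Units: f_* are volume fractions of 1; ap_mg_per_g is acidic phospholipid
# concentration in mg per g of tissue.
tissue,f_ew,f_iw,f_nl,f_np,ap_mg_per_g,f_protein
lung,0.336,0.446,0.0220,0.0128,3.91,0.10
brain,0.162,0.620,0.0390,0.0015,0.40,0.08
heart,0.320,0.456,0.0140,0.0111,2.25,0.12
kidney,0.273,0.483,0.0120,0.0240,5.03,0.13
liver,0.161,0.573,0.0140,0.0240,4.56,0.15
gut,0.282,0.475,0.0380,0.0125,2.41,0.10
spleen,0.207,0.579,0.0077,0.0113,3.18,0.10
stomach,0.282,0.475,0.0380,0.0125,2.41,0.10
muscle,0.118,0.630,0.0100,0.0072,1.53,0.14
adipose,0.135,0.017,0.8530,0.0016,0.40,0.01
skin,0.382,0.291,0.0600,0.0044,1.32,0.20
bone,0.100,0.346,0.0170,0.0017,0.67,0.10
rest,0.200,0.500,0.0400,0.0080,1.50,0.10
plasma,0.945,0.000,0.0023,0.0013,0.00,0.06
blood_cells,0.000,0.603,0.0017,0.0029,0.50,0.30
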