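# Demographic and dosing characteristics of the clinical study groups used
# for model development (non-genotyped; Geister et al.) and CYP2D6
# genotype-specific evaluation (Kirchheiner et al. 2004). Age and weight are
# ranges (min-max); the 75 mg capsule dose was given as three 25 mg
# immediate-release capsules, the genotyped groups received a 75 mg tablet.
study,compound,cyp2d6,n,female_pct,age_min,age_max,weight_min,weight_max,dose_mg,formulation
geister,doxepin,none,30,63,22,50,55.0,90.0,75,capsule_immediate
kirchheiner,doxepin,NM,19,0,23,35,50.0,93.0,75,tablet_weibull
kirchheiner,doxepin,IM,8,0,26,42,63.0,87.4,75,tablet_weibull
kirchheiner,doxepin,PM,11,0,28,56,69.4,86.2,75,tablet_weibull
kirchheiner,doxepin,UM,11,0,22,44,65.9,92.1,75,tablet_weibull
geister,nordoxepin,none,30,63,22,50,55.0,90.0,75,capsule_immediate
kirchheiner,nordoxepin,NM,19,0,23,35,50.0,93.0,75,tablet_weibull
kirchheiner,nordoxepin,IM,8,0,26,42,63.0,87.4,75,tablet_weibull
kirchheiner,nordoxepin,PM,11,0,32,60,69.4,86.2,75,tablet_weibull
kirchheiner,nordoxepin,UM,11,0,22,44,65.9,92.1,75,tablet_weibull
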