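# Observed and model-predicted PK parameters for doxepin and nordoxepin
# after a single 75 mg oral dose of doxepin, across the non-genotyped
# development population (Geister et al.) and CYP2D6 genotype groups
# (Kirchheiner et al. 2004). Units: AUC nmol*hr/L (0 to infinity),
# Cmax nmol/L, Tmax h. fold_error_printed is the published fold error
# (predicted/observed) rounded to 2 d.p., kept for regression testing of
# the fold-error arithmetic.
study,compound,cyp2d6,metric,observed,predicted,unit,fold_error_printed
geister,doxepin,none,AUC,692.47,709.02,nmol*hr/L,1.02
kirchheiner,doxepin,NM,AUC,398.00,504.66,nmol*hr/L,1.27
kirchheiner,doxepin,IM,AUC,933.00,1031.62,nmol*hr/L,1.11
kirchheiner,doxepin,PM,AUC,2291.00,2315.53,nmol*hr/L,1.01
kirchheiner,doxepin,UM,AUC,331.00,379.95,nmol*hr/L,1.15
geister,doxepin,none,Cmax,57.13,55.85,nmol/L,0.98
kirchheiner,doxepin,NM,Cmax,35.00,43.97,nmol/L,1.26
kirchheiner,doxepin,IM,Cmax,62.00,60.26,nmol/L,0.97
kirchheiner,doxepin,PM,Cmax,100.00,78.72,nmol/L,0.79
kirchheiner,doxepin,UM,Cmax,26.00,36.19,nmol/L,1.39
geister,doxepin,none,Tmax,1.98,1.40,h,0.71
geister,nordoxepin,none,AUC,1121.40,955.80,nmol*hr/L,0.85
kirchheiner,nordoxepin,NM,AUC,562.00,628.00,nmol*hr/L,1.12
kirchheiner,nordoxepin,IM,AUC,912.00,1194.33,nmol*hr/L,1.31
kirchheiner,nordoxepin,PM,AUC,1820.00,4640.32,nmol*hr/L,2.55
kirchheiner,nordoxepin,UM,AUC,200.00,342.48,nmol*hr/L,1.71
geister,nordoxepin,none,Cmax,24.64,25.10,nmol/L,1.02
kirchheiner,nordoxepin,NM,Cmax,25.00,19.14,nmol/L,0.77
kirchheiner,nordoxepin,IM,Cmax,28.00,28.42,nmol/L,1.02
kirchheiner,nordoxepin,PM,Cmax,42.00,49.53,nmol/L,1.18
kirchheiner,nordoxepin,UM,Cmax,16.00,13.42,nmol/L,0.84
geister,nordoxepin,none,Tmax,4.52,5.55,h,1.23
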