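# Reference adult physiology (73 kg) used to build virtual individuals.
# Volumes and regional blood flows are standard adult reference values
# (ICRP-style); flows are blood flows in L/min, treated as plasma-equivalent
# under the default blood:plasma partition ratio of 1. The liver flow row is
# the hepatic ARTERIAL flow only; portal inflow is routed through gut,
# spleen and stomach in the model topology. Cardiac output is the sum of
# all arterial-fed flows. Flow is empty for non-perfused pool compartments.
organ,volume_L,flow_L_min
arterial,1.70,
venous,3.60,
lung,0.50,
brain,1.45,0.70
heart,0.33,0.24
kidney,0.31,1.24
liver,1.80,0.30
gut,1.65,1.00
spleen,0.15,0.08
stomach,0.15,0.04
muscle,29.00,0.75
adipose,13.50,0.26
skin,3.30,0.30
bone,10.50,0.25
rest,4.00,0.30
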