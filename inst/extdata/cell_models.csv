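organism_id,organism,cell_dw_g,cell_volume_L,specific_volume_L_per_g,volume_source
bsub,Bacillus subtilis,2.2e-13,9e-16,4.09e-3,literature
scer,Saccharomyces cerevisiae,1.65e-11,4.4e-14,2.66e-3,literature
noce,Nannochloropsis oceanica,1.19e-11,1.4e-14,1.18e-3,literature
ptri,Phaeodactylum tricornutum,4.88e-11,1.22e-13,2.51e-3,half_parallelepiped_20x3.5x3.5um
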