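# Entity and positive-association counts of the curated public DTI
# benchmark (DrugBank/HPRD/CTD/SIDER-derived) at the scale this package
# targets.
stat	value
n_drugs	707
n_proteins	1489
n_side_effects	4192
n_diseases	5603
dti_positives	1909
ddi_positives	10024
dsie_positives	80160
ddis_positives	199022
ppi_positives	7133
pdis_positives	1572157
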