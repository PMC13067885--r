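characteristic,mci_mean,mci_sd,cn_mean,cn_sd,n_mci,n_cn
age_years,67.26,2.77,66.82,3.30,34,34
moca_score,21.71,2.22,27.15,1.12,34,34
height_cm,163.00,7.69,160.03,6.25,34,34
weight_kg,68.05,9.25,64.75,7.59,34,34
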