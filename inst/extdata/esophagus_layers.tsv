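layer	h_um	h_sd_um	eps_R	eps_R_sd	eps_S	eps_S_sd	eps_P	eps_P_sd	E_P_kPa	E_P_sd_kPa
esophagus_experimental	312.44	11.44	0.00	NA	0.43	0.06	0.43	0.06	5.11	2.32
esophagus_two_layer_model	NA	NA	NA	NA	NA	NA	NA	NA	5.06	1.04
esophagus_three_layer_model	NA	NA	NA	NA	NA	NA	NA	NA	4.22	0.74
epithelium_stroma	83.44	5.57	0.06	0.04	NA	NA	0.49	0.07	9.68	2.31
epithelium	45.6	5.53	-0.21	0.08	NA	NA	0.22	0.10	1.98	0.82
stroma	37.84	0.68	0.02	0.12	NA	NA	0.45	0.13	12.22	3.05
muscle	229.03	9.96	-0.02	0.02	NA	NA	0.41	0.06	3.26	1.29
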