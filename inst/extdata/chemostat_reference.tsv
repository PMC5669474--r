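strain	growth	dilution_rate	glucose_feed	dry_weight	dry_weight_sd	lactate	lactate_sd	formate	formate_sd	acetate	acetate_sd	ethanol	ethanol_sd	lactate_flux	lactate_flux_sd	formate_flux	formate_flux_sd	acetate_flux	acetate_flux_sd	ethanol_flux	ethanol_flux_sd	lactate_mmol_g	lactate_mmol_g_sd	formate_mmol_g	formate_mmol_g_sd	acetate_mmol_g	acetate_mmol_g_sd	ethanol_mmol_g	ethanol_mmol_g_sd	carbon_balance	carbon_balance_sd
23K	high	0.357	55.5	1.83	0.01	91.78	0.63	15.13	1.22	10.57	1.15	7.91	0.56	17.84	0.12	2.94	0.24	2.06	0.22	1.54	0.11	49.96	0.34	8.24	0.66	5.76	0.62	4.30	0.30	98.32	0.65
23K	low	0.045	55.5	1.26	0.09	76.25	4.09	29.85	3.88	20.25	3.15	15.28	1.19	2.72	0.15	1.06	0.14	0.72	0.11	0.54	0.04	60.34	3.24	23.62	3.07	16.03	2.49	12.09	0.94	99.00	0.56
LS25	high	0.357	55.5	1.78	0.04	96.00	1.79	11.61	1.78	8.01	1.03	6.93	2.36	19.23	0.36	2.33	0.36	1.61	0.21	1.39	0.47	53.88	1.00	6.52	1.00	4.50	0.58	3.89	1.32	98.95	1.31
LS25	low	0.045	55.5	1.26	0.07	56.75	0.47	46.55	0.20	26.27	0.14	24.77	0.89	2.01	0.02	1.65	0.01	0.93	0.01	0.88	0.03	44.75	0.37	36.70	0.15	20.71	0.11	19.53	0.70	95.75	0.37
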