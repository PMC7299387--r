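population	snp_id	effect_allele_freq_pct	n_individuals
HG	rs4762	14.84	1167
HG	rs5049	13.38	1167
HG	rs699	47.88	1167
HG	rs2266782	39.68	1167
HG	rs17367504	13.62	1167
HG	rs5068	4.80	1167
HG	rs198358	23.58	1167
HG	rs5186	26.22	1167
HG	rs4961	18.39	1167
HG	rs1173771	58.97	1167
HG	rs1799983	31.12	1167
HG	rs2070744	39.56	1167
HG	rs1813353	62.38	1167
HG	rs4373814	52.29	1167
HG	rs932764	46.74	1167
HG	rs2681472	83.89	1167
HG	rs5443	33.02	1167
HG	rs1378942	38.70	1167
HG	rs13333226	17.26	1167
HG	rs6015450	12.86	1167
HR	rs4762	12.81	1176
HR	rs5049	11.29	1176
HR	rs699	51.01	1176
HR	rs2266782	36.69	1176
HR	rs17367504	11.81	1176
HR	rs5068	5.56	1176
HR	rs198358	25.07	1176
HR	rs5186	13.41	1176
HR	rs4961	16.47	1176
HR	rs1173771	55.58	1176
HR	rs1799983	28.06	1176
HR	rs2070744	31.16	1176
HR	rs1813353	61.06	1176
HR	rs4373814	55.01	1176
HR	rs932764	40.65	1176
HR	rs2681472	74.59	1176
HR	rs5443	33.90	1176
HR	rs1378942	49.68	1176
HR	rs13333226	11.41	1176
HR	rs6015450	7.41	1176
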