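snp_id	locus	chromosome	effect_allele	other_allele	direction	genetic_model	effect_kind	effect_value
rs4762	AGT	1	T	C	susceptibility	per_allele	odds_ratio	1.19
rs5049	AGT	1	A	G	susceptibility	per_allele	odds_ratio	1.37
rs699	AGT	1	C	T	susceptibility	per_allele	odds_ratio	1.20
rs2266782	FMO3	1	A	G	susceptibility	per_allele	none	NA
rs17367504	MTHFR-NPPB	1	G	A	protective	per_allele	bp_beta	-0.103
rs5068	NPPA	1	G	A	protective	per_allele	odds_ratio	0.85
rs198358	NPPA-AS1	1	C	T	protective	per_allele	odds_ratio	0.90
rs5186	AGTR1	3	C	A	susceptibility	recessive	odds_ratio	7.3
rs4961	ADD1	4	T	G	susceptibility	dominant	odds_ratio	1.60
rs1173771	NPR3-C5orf23	5	G	A	susceptibility	per_allele	bp_beta	0.062
rs1799983	NOS3	7	T	G	susceptibility	per_allele	odds_ratio	1.038
rs2070744	NOS3	7	C	T	susceptibility	per_allele	odds_ratio	1.04
rs1813353	CACNB2-3p	10	T	C	susceptibility	per_allele	bp_beta	0.078
rs4373814	CACNB2-5p	10	G	C	protective	per_allele	bp_beta	-0.046
rs932764	PLCE1	10	G	A	susceptibility	per_allele	bp_beta	0.055
rs2681472	ATP2B1	12	A	G	susceptibility	per_allele	bp_beta	0.15
rs5443	GNB3	12	T	C	susceptibility	per_allele	odds_ratio	2.3
rs1378942	CYP1A1-ULK3	15	C	A	susceptibility	per_allele	bp_beta	0.073
rs13333226	UMOD	16	G	A	protective	per_allele	odds_ratio	0.87
rs6015450	GNAS-EDN3	20	G	A	susceptibility	per_allele	bp_beta	0.11
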