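snp_id	locus	chromosome	effect_allele	other_allele	direction	genetic_model	effect_kind	effect_value
rs1799998	CYP11B2	8	T	C	susceptibility	per_allele	none	NA
rs3918226	NOS3	7	T	C	susceptibility	per_allele	none	NA
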