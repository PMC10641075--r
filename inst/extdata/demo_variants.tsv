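variant_id	chrom	pos	ref_allele	alt_allele	cohort
demo_var01	chr_demo	310	A	C	proband
demo_var02	chr_demo	705	A	G	sibling
demo_var03	chr_demo	1120	T	G	proband
demo_var04	chr_demo	1534	T	G	sibling
demo_var05	chr_demo	1910	G	T	proband
demo_var06	chr_demo	2150	G	C	sibling
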