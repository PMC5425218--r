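chrom	pos	pvalue	disease	rsid
chrS1	41000	3e-09	psoriasis	rsX00001
chrS1	210000	4.9e-08	psoriasis	rsX00002
chrS1	350000	2e-10	atopic_dermatitis	rsX00003
chrS2	52940	1e-11	psoriasis	rsX00004
chrS2	1200000	3e-07	alopecia_areata	rsX00005
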