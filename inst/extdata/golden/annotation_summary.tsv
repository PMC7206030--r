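metric	value
peaks_promoter	13
peaks_exon	2
peaks_intron	2
peaks_intergenic	3
genes_total	120
genes_with_peak	18
fraction_genes_occupied	0.15000
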