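accession	source	role
TCGA-BRCA	TCGA	expression+clinical+mutation+cnv
GSE21653	GEO	expression+clinical
GSE24450	GEO	expression+clinical
GSE42568	GEO	expression+clinical
GSE45255	GEO	expression+clinical
GSE51783	GEO	expression+clinical
GSE61304	GEO	expression+clinical
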