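key	value
n_annotated_genes	13796
reads_per_gene_recommended	500
bendiocarb_mortality_pct	65.9
pbo_bendiocarb_mortality_pct	97.4
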