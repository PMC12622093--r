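# CPIC-derived activity values for the packaged star alleles (version 2026-09).
# Phenotype bins are attached by locuskit::activity_table().
star	activity
*1	1
*2	1
*4	0
*10	0.25
*17	0.5
*41	0.5
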