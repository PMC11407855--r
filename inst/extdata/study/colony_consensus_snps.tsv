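arm	n_snps
2L	2519
2R	12769
3L	1530
3R	1931
X	10510
other	0
total	29259
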