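group	feature_present	feature_absent
ase	13	102
non_ase	103	1230
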