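group	feature_present	feature_absent
ase	60	54
non_ase	481	852
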