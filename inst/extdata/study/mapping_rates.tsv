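cross	mapping_pct
B1	88.6
B3	87.1
B5	87.7
K2	85.5
K4	86.3
K6	86.9
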