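cross	n_significant	n_detectable
B1	327	6486
B3	324	6065
B5	823	7537
K2	255	5185
K4	979	8166
K6	757	7852
All	13	2934
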