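HLA-A	hla_a_02_01_01_02	hla_a_01_01
HLA-B	hla_b_07_02_01	hla_b_08_01
HLA-C	hla_c_07_01	hla_c_07_01
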