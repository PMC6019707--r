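population	allele	frequency	n
synthetic_pop1	A*02:01	0.27	2000
synthetic_pop1	A*01:01	0.20	2000
synthetic_pop1	A*03:01	0.14	2000
synthetic_pop1	B*07:02	0.17	2000
synthetic_pop1	B*08:01	0.16	2000
synthetic_pop1	C*07:02	0.19	2000
synthetic_pop1	C*05:01	0.13	2000
synthetic_pop2	A*02:01	0.24	1200
synthetic_pop2	A*03:01	0.31	1200
synthetic_pop2	B*07:02	0.19	1200
synthetic_pop2	B*15:01	0.15	1200
synthetic_pop2	C*06:02	0.07	1200
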