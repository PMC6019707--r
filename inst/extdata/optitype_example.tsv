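	A1	A2	B1	B2	C1	C2	Reads	Objective
0	A*02:01	A*01:01	B*07:02	B*08:01	C*07:01	C*07:02	1523	1478.31
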