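sample_id	locus	allele1	allele2
fam01_F	A	A*01:01	A*11:01
fam01_M	A	A*02:01	A*03:01
fam01_C	A	A*02:01	A*01:01
fam01_F	B	B*07:02	B*08:01
fam01_M	B	B*07:02	B*44:02
fam01_C	B	B*07:02	B*07:05
fam01_F	C	C*07:01	C*05:01
fam01_M	C	C*07:02	C*06:02
fam01_C	C	C*07:01	C*07:02
fam02_F	A	A*02:01	A*24:02
fam02_M	A	A*01:01	A*01:01
fam02_C	A	A*24:02	A*01:01
fam02_F	B	B*15:01	B*40:01
fam02_M	B	B*08:01	B*08:01
fam02_C	B	B*15:01	B*08:01
fam02_F	C	C*03:04	C*07:01
fam02_M	C	C*05:01	C*07:02
fam02_C	C	C*03:04	C*07:02
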