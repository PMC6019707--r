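sample_id	family_id	role
fam01_F	fam01	father
fam01_M	fam01	mother
fam01_C	fam01	child
fam02_F	fam02	father
fam02_M	fam02	mother
fam02_C	fam02	child
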