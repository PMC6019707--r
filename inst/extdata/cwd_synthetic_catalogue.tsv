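allele
A*01:01
A*02:01
A*03:01
A*11:01
A*24:02
B*07:02
B*08:01
B*15:01
B*40:01
B*44:02
C*03:04
C*05:01
C*06:02
C*07:01
C*07:02
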