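name	x	y	z
C3	-1	0	0
C4	1	0	0
Cz	0	0	1
Fz	0	1	0
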