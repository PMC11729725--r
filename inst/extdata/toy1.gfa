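H	VN:Z:1.0
S	1	ACGT
S	2	A
S	3	C
S	4	GG
L	1	+	2	+	0M
L	1	+	3	+	0M
L	2	+	4	+	0M
L	3	+	4	+	0M
P	x	1+,2+,4+	*
P	y	1+,3+,4+	*
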