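# alignhush 3x3 secondary-structure substitution table (log2 odds)
	H	E	C
H	0.876594	-1.892035	-1.602313
E	-1.892035	1.521092	-1.590605
C	-1.602313	-1.590605	1.493011
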