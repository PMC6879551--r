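column	locus	hap
L1:h1	L1	1
L1:h2	L1	2
L2:h1	L2	1
L3:h1	L3	1
L4:h1	L4	1
L5:h1	L5	1
L6:h1	L6	1
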