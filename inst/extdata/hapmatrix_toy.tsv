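sample	L1:h1	L1:h2	L2:h1	L3:h1	L4:h1	L5:h1	L6:h1
a	1	1	NA	1	1	1	NA
b	1	1	1	1	1	1	1
c	1	0	NA	1	NA	1	1
d	1	0	1	1	1	1	1
e	1	0	NA	1	1	1	1
f	1	0	1	1	1	1	1
g	1	0	NA	1	1	1	1
h	1	0	1	1	1	1	1
i	1	0	1	NA	1	NA	1
j	1	0	1	NA	1	1	1
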