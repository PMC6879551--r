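sample	location	year	length_mm
a	S	2012	31.0
b	S	2012	44.5
c	S	2013	38.2
d	S	2013	51.3
e	M	2013	47.8
f	M	2013	42.0
g	S	2014	55.1
h	S	2014	36.6
i	K	2014	49.9
j	K	2014	41.4
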