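i	j	multiplicity
7	24	1
12	24	1
13	26	1
13	38	1
16	18	1
16	24	2
16	28	1
18	20	1
20	22	1
20	28	1
20	34	1
22	22	1
22	24	1
22	31	1
22	34	1
24	26	1
24	34	3
24	38	2
28	31	1
31	34	1
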