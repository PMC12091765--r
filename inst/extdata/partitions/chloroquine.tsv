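i	j	multiplicity
7	23	1
12	24	2
12	35	1
15	23	1
15	25	1
16	18	1
16	23	1
18	20	2
18	25	1
20	20	1
20	22	1
20	28	1
20	31	1
20	34	1
22	31	1
22	35	2
24	34	2
25	28	1
28	31	1
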