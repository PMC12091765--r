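i	j	multiplicity
9	30	1
12	37	1
13	40	1
15	46	2
16	49	3
20	30	1
20	34	1
22	31	2
22	37	2
24	34	2
24	40	2
26	28	3
26	37	3
28	28	2
28	30	2
28	40	2
28	46	1
30	30	2
30	31	1
32	34	1
32	46	1
34	34	4
34	49	3
40	43	1
43	46	2
46	49	3
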