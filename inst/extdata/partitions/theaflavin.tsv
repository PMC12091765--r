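i	j	multiplicity
10	31	2
11	32	1
11	33	1
11	34	1
12	37	1
13	40	1
15	44	1
15	46	2
18	27	1
18	31	1
20	28	1
20	32	1
21	31	1
21	33	1
22	31	1
22	37	1
24	34	2
24	38	1
24	40	1
26	37	1
26	41	1
27	28	2
28	31	3
28	38	1
28	40	2
28	44	2
28	46	1
30	46	2
31	32	1
31	33	1
31	34	2
34	37	1
37	38	1
37	40	1
40	41	1
41	46	1
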