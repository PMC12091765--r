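i	j	multiplicity
12	37	1
14	43	3
15	46	1
16	49	1
17	52	1
21	64	2
24	37	2
26	37	2
26	43	2
28	40	1
28	46	1
30	32	2
30	43	2
32	32	2
32	46	2
32	52	2
34	49	1
34	55	1
36	38	3
36	52	3
37	40	1
38	38	2
38	39	1
38	55	2
38	60	1
38	61	1
39	60	1
40	43	1
42	43	2
42	61	2
43	43	1
43	46	1
46	49	1
60	64	1
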