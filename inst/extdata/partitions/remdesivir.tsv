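i	j	multiplicity
10	42	1
12	37	2
13	39	1
13	40	1
13	53	1
17	34	2
17	52	1
20	20	1
20	34	1
20	42	1
22	37	2
22	42	2
24	34	1
24	53	1
26	28	2
26	37	2
28	28	2
28	30	1
28	40	1
30	31	1
30	43	1
30	49	1
31	48	1
32	34	1
32	46	1
34	34	1
34	37	1
34	49	2
34	52	1
37	39	1
37	40	1
39	53	1
43	46	1
43	53	1
46	48	1
48	52	1
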