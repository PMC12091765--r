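i	j	multiplicity
7	22	1
8	25	1
10	20	1
10	30	2
11	34	2
14	16	1
14	21	1
16	28	1
18	20	1
18	24	1
18	25	1
18	30	1
20	22	2
20	28	3
20	34	1
21	22	2
22	22	2
22	24	2
22	25	1
24	24	1
24	28	1
28	30	1
30	30	1
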