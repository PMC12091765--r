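i	j	multiplicity
6	19	3
8	23	1
12	14	1
12	17	1
14	19	1
14	23	2
16	17	2
16	21	2
17	17	2
17	19	3
19	21	2
21	21	1
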