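property	R2	SE	F	A	B	p	indicator
BP	0.766	128.221	16.358	461.302	0.008	0.0098	Sign
E	0.758	18.992	15.693	73.949	0.001	0.0107	Sign
FP	0.869	48.579	33.296	216.346	0.004	0.0021	Sign
MR	0.903	16.161	46.657	76.630	0.002	0.0010	Sign
PSA	0.631	48.791	8.566	44.467	0.002	0.0327	Sign
P	0.904	6.376	47.152	30.361	0.001	0.0010	Sign
MV	0.787	75.978	18.509	204.494	0.005	0.0076	Sign
MW	0.884	64.937	38.274	283.776	0.006	0.0016	Sign
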