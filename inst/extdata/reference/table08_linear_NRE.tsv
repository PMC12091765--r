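property	R2	SE	F	A	B	p	indicator
BP	0.681	149.580	10.694	520.403	8.484E-5	0.0221	Sign
E	0.675	22.023	10.390	82.515	1.231E-5	0.0233	Sign
FP	0.846	52.729	27.505	243.722	4.797E-5	0.0033	Sign
MR	0.864	19.179	31.681	87.770	1.872E-5	0.0024	Sign
PSA	0.589	51.527	7.164	59.530	2.392E-5	0.0439	Sign
P	0.865	7.568	32.015	34.777	7.428E-6	0.0023	Sign
MV	0.774	78.312	17.128	235.801	5.622E-5	0.0090	Sign
MW	0.832	78.362	24.717	325.550	6.758E-5	0.0042	Sign
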