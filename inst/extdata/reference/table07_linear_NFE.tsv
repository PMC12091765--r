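property	R2	SE	F	A	B	p	indicator
BP	0.771	126.816	16.834	460.990	0.004	0.0093	Sign
E	0.764	18.789	16.143	73.901	0.001	0.0101	Sign
FP	0.864	49.561	31.793	217.017	0.002	0.0024	Sign
MR	0.901	16.320	45.659	76.790	0.001	0.0010	Sign
PSA	0.641	48.187	8.909	44.125	0.001	0.0306	Sign
P	0.902	6.439	46.135	30.425	0.0002	0.0010	Sign
MV	0.781	77.072	17.846	205.407	0.002	0.0082	Sign
MW	0.886	64.443	38.939	283.974	0.003	0.0015	Sign
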