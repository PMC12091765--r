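property	R2	SE	F	A	B	p	indicator
BP	0.639	159.231	8.849	-447.691	863.007	0.0309	Sign
E	0.635	23.358	8.681	-58.175	125.390	0.0320	Sign
FP	0.401	104.066	3.345	-115.175	346.785	0.1269	Insign
MR	0.366	41.353	2.890	-42.589	128.076	0.1499	Insign
PSA	0.564	53.039	6.480	-216.997	246.002	0.0515	Insign
P	0.366	16.393	2.890	-16.890	50.772	0.1498	Insign
MV	0.214	146.039	1.363	-56.919	310.632	0.2956	Insign
MW	0.531	130.771	5.671	-285.306	567.372	0.0630	Sign
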