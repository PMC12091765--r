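property	R2	SE	F	A	B	p	indicator
BP	0.954	56.753	104.016	106.844	7.299	0.0001	Sign
E	0.944	9.161	83.948	22.568	1.058	0.0002	Sign
FP	0.813	58.136	21.740	67.920	3.418	0.0055	Sign
MR	0.878	18.168	35.876	16.040	1.372	0.0018	Sign
PSA	0.760	39.408	15.796	-50.284	1.975	0.0105	Sign
P	0.878	7.198	35.916	6.350	0.544	0.0018	Sign
MV	0.677	93.641	10.476	44.838	3.822	0.0230	Sign
MW	0.953	41.503	100.936	41.637	5.258	0.0001	Sign
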