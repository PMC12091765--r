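property	R2	SE	F	A	B	p	indicator
BP	0.688	148.136	11.001	515.933	0.001	0.0210	Sign
E	0.681	21.820	10.678	81.868	0.0002	0.0222	Sign
FP	0.854	51.386	29.227	241.187	0.001	0.0029	Sign
MR	0.870	18.745	33.398	86.284	0.0003	0.0021	Sign
PSA	0.588	51.593	7.133	58.555	0.0003	0.0443	Sign
P	0.871	7.396	33.756	34.401	0.0001	0.0021	Sign
MV	0.780	77.200	17.770	232.885	0.001	0.0083	Sign
MW	0.837	77.148	25.659	322.196	0.001	0.0038	Sign
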