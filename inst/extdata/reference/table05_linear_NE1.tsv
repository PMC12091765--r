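property	R2	SE	F	A	B	p	indicator
BP	0.857	100.264	29.928	352.791	0.171	0.0027	Sign
E	0.848	15.082	27.815	58.230	0.025	0.0032	Sign
FP	0.872	48.019	34.195	167.758	0.087	0.0020	Sign
MR	0.926	14.088	62.981	56.712	0.035	0.0005	Sign
PSA	0.679	45.506	10.596	16.457	0.046	0.0225	Sign
P	0.927	5.564	63.476	22.468	0.014	0.0005	Sign
MV	0.777	77.781	17.431	149.562	0.101	0.0086	Sign
MW	0.933	49.274	70.157	207.541	0.129	0.0003	Sign
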