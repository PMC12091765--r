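index	BP	E	FP	MR	PSA	P	MV	MW
NE1	0.980	0.976	0.938	0.976	0.842	0.976	0.906	0.981
NE2	0.966	0.962	0.949	0.966	0.814	0.966	0.891	0.966
NFE	0.969	0.964	0.945	0.966	0.820	0.966	0.889	0.968
NRE	0.962	0.958	0.963	0.958	0.819	0.958	0.888	0.956
NSDdegE	0.978	0.972	0.919	0.938	0.876	0.938	0.833	0.977
NISIE	0.978	0.974	0.942	0.977	0.836	0.977	0.907	0.981
NHE	0.838	0.834	0.634	0.615	0.751	0.615	0.466	0.734
NAE	0.962	0.957	0.964	0.959	0.818	0.959	0.891	0.957
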