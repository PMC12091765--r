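index	BP	E	FP	MR	PSA	P	MV	MW
NE1	0.926	0.921	0.934	0.961	0.828	0.961	0.878	0.968
NE2	0.875	0.871	0.932	0.950	0.799	0.950	0.885	0.944
NFE	0.878	0.874	0.930	0.948	0.806	0.949	0.881	0.945
NRE	0.825	0.822	0.920	0.930	0.771	0.931	0.879	0.916
NSDdegE	0.977	0.971	0.902	0.935	0.873	0.935	0.821	0.978
NISIE	0.923	0.918	0.937	0.962	0.821	0.963	0.883	0.967
NHE	0.799	0.797	0.633	0.606	0.702	0.606	0.466	0.717
NAE	0.829	0.825	0.924	0.934	0.770	0.934	0.883	0.919
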