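drug	actual	NE1	NE2	NFE	NRE	NSDdegE	NISIE	NHE	NAE
arbidol	80	78.787	73.219	76.214	75.434	93.083	78.829	142.510	71.685
chloroquine	28.2	64.711	68.117	70.144	73.424	52.441	65.302	41.009	69.907
hydroxychloroquine	48.4	70.185	72.651	75.023	77.219	56.797	70.891	36.089	72.952
lopinavir	120	164.163	148.439	158.626	148.033	172.694	164.847	164.207	129.055
remdesivir	204	152.249	141.785	153.935	145.525	158.056	150.838	120.345	125.598
ritonavir	202	206.621	202.589	219.787	218.276	192.774	206.624	129.127	181.700
thalidomide	83.6	48.933	56.087	56.765	64.432	45.754	49.445	97.959	62.876
theaflavin	218	144.705	126.575	136.525	123.342	166.604	143.546	169.299	108.811
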