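drug	actual	NE1	NE2	NFE	NRE	NSDdegE	NISIE	NHE	NAE
arbidol	48.3	41.438	44.737	36.842	39.716	45.839	41.123	57.308	38.777
chloroquine	38.6	37.154	42.186	35.6288	39.091	34.644	37.030	36.359	38.185
hydroxychloroquine	39.2	38.82	44.453	36.604	40.270	35.844	38.721	35.344	39.2
lopinavir	71	67.422	82.347	53.325	62.260	67.767	67.149	61.786	57.901
remdesivir	59.3	63.796	79.02	52.387	61.481	63.735	62.910	52.733	56.748
ritonavir	78.9	80.344	109.422	65.557	84.073	73.298	79.789	54.546	75.449
thalidomide	25.9	32.352	36.171	32.953	36.299	32.803	32.232	48.113	35.841
theaflavin	54.4	61.5	71.415	48.905	54.592	66.090	60.704	62.837	51.153
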