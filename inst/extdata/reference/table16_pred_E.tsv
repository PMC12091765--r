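drug	actual	NE1	NE2	NFE	NRE	NSDdegE	NISIE	NHE	NAE
arbidol	91.5	92.105	88.325	105.99	90.700	99.369	91.658	125.069	90.621
chloroquine	72.1	84.455	85.774	99.92	89.665	77.597	84.374	73.334	89.436
hydroxychloroquine	83	87.43	88.041	104.799	91.618	79.931	87.383	70.826	91.466
lopinavir	140.8	138.505	125.935	188.402	128.061	142.016	137.975	136.129	128.868
remdesivir	NA	132.03	122.608	183.711	126.771	134.175	130.432	113.772	126.563
ritonavir	144.4	161.58	153.01	249.563	164.211	152.773	160.470	118.248	163.964
thalidomide	79.4	75.88	79.759	86.541	85.037	74.015	75.836	102.361	84.749
theaflavin	153.5	127.93	115.003	166.301	115.354	138.754	126.506	138.724	115.372
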