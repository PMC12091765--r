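drug	actual	NE1	NE2	NFE	NRE	NSDdegE	NISIE	NHE	NAE
arbidol	121.9	104.137	105.382	108.879	100.217	115.635	103.506	391.616	99.414
chloroquine	97.4	93.427	100.28	102.809	98.643	87.401	93.239	248.533	97.636
hydroxychloroquine	99	97.592	104.814	107.688	101.614	90.427	97.481	241.597	100.681
lopinavir	179.2	169.097	180.602	191.291	157.033	170.939	168.792	422.203	156.784
remdesivir	149.5	160.032	173.948	186.6	155.070	160.770	158.159	360.371	153.327
ritonavir	198.9	201.402	234.752	252.452	212.006	184.888	200.499	372.751	209.429
thalidomide	65.2	81.422	88.25	89.43	91.606	82.756	81.204	328.813	90.605
theaflavin	137.3	154.292	158.738	169.19	137.710	166.708	152.625	429.381	136.540
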