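drug	actual	NE1	NE2	NFE	NRE	NSDdegE	NISIE	NHE	NAE
arbidol	347.3	286.417	276.374	269.585	273.183	322.281	285.568	397.038	276.653
chloroquine	287.9	255.511	263.619	257.445	268.457	243.630	255.6	268.871	270.727
hydroxychloroquine	285.4	267.53	274.954	267.203	277.378	252.060	267.981	262.659	280.875
lopinavir	540.5	473.873	464.424	434.409	443.814	476.344	476.131	424.436	467.887
remdesivir	409	447.714	447.789	425.027	437.919	448.016	445.096	369.050	456.362
ritonavir	581.7	567.096	599.799	556.731	608.908	515.201	568.682	380.140	643.368
thalidomide	161	220.868	233.544	230.687	247.322	230.69	220.47	340.783	247.29
theaflavin	301	431.15	409.764	390.207	385.781	464.557	428.941	430.866	400.405
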