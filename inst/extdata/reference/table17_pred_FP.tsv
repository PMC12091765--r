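drug	actual	NE1	NE2	NFE	NRE	NSDdegE	NISIE	NHE	NAE
arbidol	311.7	285.643	273.85	281.195	275.618	316.036	285.404	391.62	284.955
chloroquine	232.3	259.021	263.646	269.055	271.586	245.699	259.529	248.53	279.029
hydroxychloroquine	266.3	269.374	272.714	278.813	279.198	253.238	270.219	241.6	289.177
lopinavir	512.7	447.115	424.29	446.019	421.210	453.814	449.942	422.2	476.189
remdesivir	NA	424.582	410.982	436.637	416.180	428.480	423.145	360.37	464.664
ritonavir	526.6	527.416	532.59	568.341	562.077	488.564	529.852	372.75	651.670
thalidomide	248.8	229.18	239.586	242.297	253.552	234.127	229.197	328.81	255.592
theaflavin	336.5	410.314	380.562	401.817	371.693	443.273	409.196	429.38	408.707
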