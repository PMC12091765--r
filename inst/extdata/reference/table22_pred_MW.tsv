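drug	actual	NE1	NE2	NFE	NRE	NSDdegE	NISIE	NHE	NAE
arbidol	477.4	382.336	370.032	380.241	370.485	423.321	381.022	543.851	365.964
chloroquine	319.9	342.862	354.726	362.031	364.804	315.119	343.077	309.753	360.038
hydroxychloroquine	335.9	358.213	368.328	376.668	375.528	326.717	358.754	298.406	370.186
lopinavir	628.8	621.76	595.692	627.477	575.595	635.268	622.314	593.893	557.198
remdesivir	602.6	588.349	575.73	613.404	568.508	596.297	583.017	492.731	545.673
ritonavir	720.9	740.827	758.142	810.96	774.048	688.725	739.502	512.986	732.679
thalidomide	258.23	298.615	318.636	321.894	339.399	297.317	298.595	441.100	336.601
theaflavin	564.5	567.193	530.1	561.174	505.835	619.053	562.561	605.638	489.716
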