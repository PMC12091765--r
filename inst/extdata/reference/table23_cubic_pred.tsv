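drug	BP_actual	BP_NE1	E_actual	E_NE1	FP_actual	FP_NAE	MR_actual	MR_NISIE
arbidol	591.8	549.44	91.5	89.76	311.7	275.59	121.9	112.11
chloroquine	460.6	493.82	72.1	80.92	232.3	274.5	97.4	95.02
hydroxychloroquine	516.7	513.9	83	84.04	266.3	276.91	99	102.71
lopinavir	924.2	866.89	140.8	153.16	512.7	593.76	179.2	157.57
remdesivir	NA	853.37	NA	147.95	NA	569.58	149.5	151.3
ritonavir	947	723.25	144.4	144.19	526.6	710.92	198.9	195.44
thalidomide	487.8	450.74	79.4	74.85	248.8	279.51	65.2	67.62
theaflavin	1003.9	836.02	153.5	143.46	336.5	448.51	137.3	148.6
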