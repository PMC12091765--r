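drug	PSA_actual	PSA_NSDdegE	P_actual	P_NISIE	MV_actual	MV_NISIE	MW_actual	MW_NE1	MW_NISIE
arbidol	80	80.9	48.3	51.83	347.3	276.84	477.4	548.24	421.8
chloroquine	28.2	54.58	38.6	42.12	287.9	243.43	319.9	424.85	351.04
hydroxychloroquine	48.4	56.79	39.2	46.29	285.4	259.82	335.9	473.46	382.27
lopinavir	120	169.27	71	105.23	540.5	217.39	628.8	1348.48	650.25
remdesivir	204	149.37	59.3	95.21	409	234.61	602.6	1215.63	621.45
ritonavir	202	199.26	78.9	146.16	581.7	233.17	720.9	1938.71	777.77
thalidomide	83.6	51.47	25.9	28.85	161	174.19	258.23	278.2	245.02
theaflavin	218	160.79	54.4	90.46	301	245.27	564.5	1137.07	607.22
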