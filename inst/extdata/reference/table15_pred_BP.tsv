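drug	actual	NE1	NE2	NFE	NRE	NSDdegE	NISIE	NHE	NAE
arbidol	591.8	584.496	576.31	589.346	576.815	636.687	583.584	813.507	559.701
chloroquine	460.6	532.17	555.902	565.066	569.683	486.484	533.291	457.430	553.775
hydroxychloroquine	516.7	552.519	574.038	584.582	583.146	502.584	554.069	440.170	563.923
lopinavir	924.2	901.872	877.19	918.994	834.310	930.905	903.395	889.624	750.935
remdesivir	NA	857.583	850.574	900.23	825.413	876.806	851.310	735.750	739.410
ritonavir	947	1059.705	1093.79	1163.638	1083.448	1005.112	1058.717	766.559	926.416
thalidomide	487.8	473.517	507.782	511.55	537.789	461.772	474.334	657.216	530.338
theaflavin	1003.9	829.539	789.734	830.59	746.733	908.396	824.198	907.488	683.453
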