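drug	NE1	NE2	NFE	NRE	NSDdegE	NISIE	NHE	NAE
arbidol	1355	14376	32089	664924	72.5912	318.2806	1.4614	43768.2669
chloroquine	1049	11825	26019	580864	52.0127	248.9108	1.0488	37842.6494
hydroxychloroquine	1168	14092	30898	739548	54.2184	277.5706	1.0288	47990.9784
lopinavir	3211	51986	114501	3699994	112.9006	759.3995	1.5496	235002.9451
remdesivir	2952	48659	109810	3595128	105.4888	687.5585	1.3713	223477.2482
ritonavir	4134	79061	175662	6636558	123.0674	973.6367	1.407	410483.7478
thalidomide	706	5810	12640	204938	48.627	167.5911	1.2803	14405.363
theaflavin	2788	41054	92400	2667738	109.8168	650.1624	1.5703	167520.7917
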