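drug	V	E
arbidol	29	31
chloroquine	22	23
hydroxychloroquine	23	24
lopinavir	46	49
remdesivir	41	44
ritonavir	50	53
thalidomide	19	21
theaflavin	41	46
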