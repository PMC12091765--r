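property	R2	SE	F	A	B	p	indicator
BP	0.852	102.113	28.675	352.831	0.725	0.0030	Sign
E	0.842	15.346	26.696	58.239	0.105	0.0035	Sign
FP	0.878	47.045	35.835	166.686	0.373	0.0018	Sign
MR	0.929	13.852	65.318	56.401	0.148	0.0004	Sign
PSA	0.671	46.101	10.196	16.765	0.195	0.0241	Sign
P	0.929	5.470	65.851	22.345	0.059	0.0004	Sign
MV	0.784	76.649	18.098	148.071	0.432	0.0080	Sign
MW	0.932	49.738	68.762	206.923	0.547	0.0004	Sign
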