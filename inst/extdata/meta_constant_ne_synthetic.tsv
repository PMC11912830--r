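id	date	coverage
IND01	63	0.85
IND02	95	2.95
IND03	56	2.76
IND04	67	1.92
IND05	65	0.76
IND06	31	2.28
IND07	223	0.76
IND08	186	3.41
IND09	175	3.82
IND10	230	2.86
IND11	239	2.22
IND12	244	1.77
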