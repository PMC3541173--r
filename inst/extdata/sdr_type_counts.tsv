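species	total	classical	divergent	extended	atypical	unknown
Arabidopsis	178	90	1	72	8	7
Poplar	268	122	4	106	16	20
Grapevine	205	95	2	88	14	6
Soybean	315	145	4	138	15	13
Rice	227	110	2	95	10	10
Maize	230	97	3	113	7	10
Sorghum	237	106	2	114	7	8
Selaginella	142	64	1	55	5	17
Physcomitrella	126	59	2	55	0	10
Chlamydomonas	68	41	1	21	1	4
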