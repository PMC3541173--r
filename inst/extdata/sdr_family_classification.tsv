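representative_gene	family_id	occurrence	starred	average_identity
AT4G23420	SDR7C	ViridP	FALSE	49.4
AT1G67730	SDR12C	LandP	FALSE	48.4
AT3G12800	SDR17C	ViridP	FALSE	64.1
AT4G05530	SDR25C	ViridP	FALSE	67.7
AT3G03330	SDR34C	ViridP	FALSE	56.1
AT3G06060	SDR35C	ViridP	FALSE	47.9
AT4G09750	SDR40C	ViridP	TRUE	70.8
AT1G54870	SDR57C	ViridP	FALSE	58.0
AT5G06060	SDR65C	ViridP	FALSE	53.3
AT3G03980	SDR68C	TracheoP	FALSE	57.0
AT5G54190	SDR73C	ViridP	FALSE	74.5
AT3G50560	SDR84C	ViridP	FALSE	60.4
AT1G52340	SDR110C	LandP	FALSE	47.1
AT3G61220	SDR114C	ViridP	FALSE	45.4
AT5G50600	SDR119C	LandP	FALSE	44.4
AT3G55290	SDR132C	ViridP	FALSE	62.4
AT1G24360	SDR152C	ViridP	FALSE	68.3
AT1G10310	SDR357C	TracheoP	FALSE	70.0
AT5G10050	SDR368C	ViridP	FALSE	45.8
AT4G27760	SDR369C	ViridP	FALSE	57.2
AT2G05990	SDR87D	ViridP	FALSE	75.0
AT1G49670	NA	ViridP	FALSE	50.6
AT3G01980	NA	LandP	FALSE	57.8
AT4G13250	NA	ViridP	FALSE	48.1
AT4G20760	NA	ViridP	FALSE	61.8
AT5G04070	NA	LandP	FALSE	52.7
AT4G10960	SDR1E	ViridP	FALSE	55.4
AT1G78570	SDR2E	ViridP	FALSE	74.7
AT5G66280	SDR3E	LandP	FALSE	72.3
AT1G17890	SDR4E	LandP	FALSE	73.1
AT2G28760	SDR6E	ViridP	FALSE	69.7
AT2G20360	SDR22E	ViridP	FALSE	60.1
AT1G47290	SDR31E	ViridP	FALSE	48.2
AT2G33630	SDR42E	ViridP	TRUE	66.2
AT4G30440	SDR50E	ViridP	FALSE	61.3
AT4G33030	SDR52E	ViridP	FALSE	73.8
AT1G08200	SDR67E	LandP	FALSE	81.9
AT5G28840	SDR93E	ViridP	FALSE	87.4
AT5G42800	SDR108E	ViridP	FALSE	36.6
GRMZM2G086773	SDR115E	FlowerP	FALSE	55.0
AT5G22500	SDR117E	LandP	FALSE	46.8
AT4G24220	SDR75U	LandP	FALSE	53.4
AT4G35250	SDR81U	ViridP	FALSE	76.4
AT1G09340	SDR83U	ViridP	FALSE	50.7
AT5G18660	SDR98U	ViridP	FALSE	62.5
AT5G02240	SDR358U	ViridP	TRUE	68.9
AT1G32100	SDR460A	TracheoP	FALSE	45.3
AT4G33360	NA	LandP	FALSE	63.2
AT4G00560	NA	ViridP	FALSE	56.5
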