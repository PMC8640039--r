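rank	SBM20	SBM40
1	5-methylbenzimidazole	5-methylbenzimidazole
2	Glycitin	Glycitin
3	Genistin	Genistin
4	Malonylglycitin	Malonylglycitin
5	Genistein 4'-O-glucuronide	Genistein 4'-O-glucuronide
6	Glycitein	Glycitein
7	Daidzein	Daidzein
8	FMNH2	FMNH2
9	Soyasaponin I	Soyasaponin I
10	olmelin	olmelin
11	Genistein	Genistein
12	Ginsenoside Ro	Ginsenoside Ro
13	4-Phenolsulfonic acid	4-Phenolsulfonic acid
14	amfonelic acid	amfonelic acid
15	Byakangelicol	Cys-Tyr
16	3,4-dihydroxyphenylacetic acid	Indole-3-butyric acid
17	Baicalin	3-Methoxyflavone
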