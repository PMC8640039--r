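level	mode	rank	metabolite
SBM20	positive	1	5-methylbenzimidazole
SBM20	positive	2	Glycitin
SBM20	positive	3	Byakangelicol
SBM20	positive	4	Genistin
SBM20	positive	5	Malonylglycitin
SBM20	positive	6	Genistein 4'-O-glucuronide
SBM20	positive	7	Glycitein
SBM20	positive	8	amfonelic acid
SBM20	positive	9	3,4-dihydroxyphenylacetic acid
SBM20	positive	10	Daidzein
SBM20	negative	1	FMNH2
SBM20	negative	2	Glycitein
SBM20	negative	3	Soyasaponin I
SBM20	negative	4	olmelin
SBM20	negative	5	Genistein
SBM20	negative	6	Ginsenoside Ro
SBM20	negative	7	4-Phenolsulfonic acid
SBM20	negative	8	Daidzein
SBM20	negative	9	Baicalin
SBM20	negative	10	Glycitin
SBM40	positive	1	amfonelic acid
SBM40	positive	2	Genistin
SBM40	positive	3	Glycitin
SBM40	positive	4	3-Methoxyflavone
SBM40	positive	5	Daidzin
SBM40	positive	6	5-methylbenzimidazole
SBM40	positive	7	Glycitein
SBM40	positive	8	Malonylglycitin
SBM40	positive	9	Genistein 4'-O-glucuronide
SBM40	positive	10	Genistein
SBM40	negative	1	FMNH2
SBM40	negative	2	Soyasaponin I
SBM40	negative	3	Ginsenoside Ro
SBM40	negative	4	4-Phenolsulfonic acid
SBM40	negative	5	Glycitein
SBM40	negative	6	Genistein
SBM40	negative	7	Cys-Tyr
SBM40	negative	8	Indole-3-butyric acid
SBM40	negative	9	Glycitin
SBM40	negative	10	olmelin
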