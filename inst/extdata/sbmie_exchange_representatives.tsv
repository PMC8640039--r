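metabolite	direction	content_mean_control	content_mean_treatment	content_trend	content_p	tissue_mean_control	tissue_mean_treatment	tissue_trend	tissue_p
Docosahexaenoic acid	content_up	430387933	583271866	up	5.66e-05	238785562	200036643	down	0.047525
Araloside A	content_up	3678.8247	19220.584	up	0.000958	5359.7504	2446.7346	down	0.014338
Embelin	content_up	3347.9281	7157.7361	up	0.044519	17008.312	10600.861	down	0.056358
Leu-arg	content_up	30402.535	74371.235	up	0.000818	273255.73	116795.89	down	0.007869
Ginkgoic acid	content_up	36804.431	106204.22	up	0.003378	38980.066	16631.79	down	0.000675
carglumic acid	content_up	719426.5	2170944.2	up	0.003613	1403067.2	187029.51	down	1.11e-11
L-Norleucine	content_up	26973473	49992149	up	0.004128	9281831	43446832	down	0.000194
Leucylproline	content_up	1236607.4	2332670.6	up	0.013949	1930426.2	907885.44	down	0.000969
L-(-)-Asparagine	content_up	268364.2	754026.74	up	0.014648	721920.86	388931.09	down	0.002853
Asp-leu	content_up	892558.05	1608231.6	up	0.02594	3402511.1	1853689	down	0.000603
Cytosine	content_down	74390.77	25886.01	down	0.002471	2765.373	4832.989	up	0.028388
Cytidine	content_down	1329923	568340.1	down	0.045209	38378.71	57443.91	up	0.068651
Indole-3-carbidol	content_down	2518362	607860.9	down	2.79e-06	49120.75	85215.99	up	0.02546
3-(Methylsulfinyl)-L-alanine	content_down	116643.8	40506.25	down	0.000317	10994.99	22349.21	up	0.004779
2-Quinolinecarboxylic acid	content_down	67407.39	33841.96	down	0.003245	20500.78	50827.34	up	0.000291
Testosterone isocaproate	content_down	1565093	598249.9	down	0.003264	465055.5	874153	up	0.021607
Tetrahydrodeoxycorticosterone	content_down	882945.4	131680.4	down	0.003446	261081.9	589995.1	up	0.003542
Estradiol enanthate	content_down	2538970	833770	down	0.005138	1539054	3029863	up	0.012127
Nicotinamide	content_down	5662292	2868804	down	0.035091	43105748	93606025	up	7.92e-11
Valeroidine	content_down	98929.59	50391.05	down	0.046873	3919.717	14900.88	up	0.000232
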