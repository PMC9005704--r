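te_id	statistic	frequency	gene_symbol	te_location
2L_14003409_14003462_Rt1a	nSL	0.15	-	Intergenic
2L_8992666_8992668_pogo	nSL	0.15	CG9555	INTRON
2R_11394154_11394156_pogo	nSL	0.17	sprt	INTRON
2R_12185376_12185380_accord	nSL	0.62	Cyp6g1	PROMOTER
2R_14078395_14078397_hopper	nSL	0.11	Prosap	INTRON
2R_18807888_18807894_BS	nSL	0.62	CG15096	3UTR
3L_12863739_12863742_Transpac	nSL	0.19	CG10943	PROMOTER
3L_14050243_14050245_pogo	nSL	0.28	CG6833;Neurl4	PROMOTER
3L_2426710_2426713_pogo	nSL	0.19	Svil	INTRON
3L_3798612_3798621_1360	nSL	0.30	CG32264	INTRON
3R_20502048_20502058_Doc	nSL	0.28	Dic2;CG46441	PROMOTER
3R_21385503_21385506_pogo	nSL	0.19	-	Intergenic
3R_29952746_29952748_Invader4	nSL	0.23	TkR99D	INTRON
X_15012530_15012533_mdg3	nSL	0.60	hiw	INTRON
X_20759991_20759993_BS3	nSL	0.57	-	Intergenic
X_2431713_2431716_Doc	nSL	0.13	-	Intergenic
X_8027468_8027478_Doc6	nSL	0.26	Tbh	3UTR
3L_18931204_18931207_F-element	nSL	0.15	CG32204	INTRON
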