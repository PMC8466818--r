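genotype	chemotype	marker_phenotype	sampling	cbd_pct	cbg_pct	thc_pct	cbc_pct
Santhica 27	IV	BD/BD	123	0.26	1.55	0.04	<LOD
Carmagnola	III	BD/BD	151	5.32	0.28	0.16	<LOQ
Bernabeo	IV	BD/BD	151	0.74	2.69	0.04	<LOQ
Carmaleonte	III	BD/BD	123	1.92	0.10	0.10	<LOQ
CS	III	BD/BD	151	5.49	0.20	0.17	<LOQ
Ermo	V	BD/BD	151	0.05	<LOD	<LOD	<LOD
Fibrante	III	BD/BD	151	3.61	0.09	0.13	<LOQ
Fibranova	III	BD/BD	151	2.34	0.10	0.07	<LOQ
Eletta Campana	III	BD/BD	151	3.85	0.17	0.11	<LOQ
Codimono	III	BD/BD	123	4.02	0.15	0.14	<LOQ
Futura 75	III	BD/BD	123	2.34	0.12	0.07	<LOD
CINBOL	I	BT/BT	50	0.01	0.37	3.71	0.01
CINRO	II	BT/BD	50	2.43	0.27	1.57	0.02
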