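# Transcribed reference table of genes carrying two or more different
# heterozygous variants that segregated across two or more families (long
# format: one row per family x variant). case_control_p is the single-variant
# p-value looked up in a separately sequenced sporadic case-control cohort
# and is carried as annotation only. An empty rsid means the variant had no
# dbSNP identifier.
family_id	chrom	pos	rsid	gene	accession	codon_change	protein_change	case_control_p	cadd_phred
18	1	94502780	NA	ABCA4	NM_000350	c.3734G>A	p.S1245N	NA	21.2
14	1	94508969	rs61751374	ABCA4	NM_000350	c.3113C>T	p.A1038V	0.800	20.5
7	3	183905991	rs566108440	ABCF3	NM_001351298	c.614G>A	p.R205Q	0.797	26.1
2	3	183908940	rs779795407	ABCF3	NM_001351298	c.1448C>T	p.P483L	NA	35
17	2	241815411	rs140992177	AGXT	NM_000030	c.836T>C	p.I279T	0.201	23.3
1	2	241810796	rs121908524	AGXT	NM_000030	c.454T>A	p.F152I	0.588	28.3
7	16	1394822	rs148966323	BAIAP3	NM_001199096	c.1673C>T	p.T558I	0.496	25.2
2	16	1394491	rs114280977	BAIAP3	NM_001199096	c.1516G>A	p.D506N	0.052	22
2	8	139833569	rs145361557	COL22A1	NM_152888	c.1055G>A	p.R352Q	0.823	23.1
12	8	139838971	rs72731614	COL22A1	NM_152888	c.899G>A	p.R300Q	NA	23.8
18	1	34015872	rs149704396	CSMD2	NM_052896	c.8390G>A	p.R2797Q	0.079	22.8
14	1	34066488	rs755952714	CSMD2	NM_001281956	c.6833G>A	p.G2278E	NA	24.9
1	17	1944871	rs200625064	DPH1	NM_001346576	c.778C>T	p.Q260X	NA	35
2	17	1943099	rs80150196	DPH1	NM_001346576	c.326C>G	p.P109R	0.429	28.4
4	16	15733081	rs150196755	MARF1	NM_001184998	c.10G>A	p.G4R	0.718	28.6
6	16	15729650	rs192438053	MARF1	NM_001184998	c.694G>A	p.G232R	0.495	25.8
1	6	138655606	rs777828045	ARFGEF3	NM_020340	c.5624_5626del	p.1875_1876del	0.795	NA
2	6	138615130	rs755891726	ARFGEF3	NM_020340	c.3369G>T	p.R1123S	0.799	25.3
18	1	109740175	rs940837035	KIAA1324	NM_001284353	c.1188_1189del	p.I396fs	0.582	NA
4	1	109734349	rs41279690	KIAA1324	NM_001284353	c.533G>A	p.G178D	0.374	23.3
15	8	28989925	rs145324154	KIF13B	NM_015254	c.2842G>A	p.A948T	0.573	32
11	8	29102864	NA	KIF13B	NM_015254	c.148C>G	p.R50G	NA	27.8
13	7	91871373	rs34358665	KRIT1	NM_001350672	c.77G>A	p.R26Q	0.542	23.6
12	7	91851344	NA	KRIT1	NM_001013406	c.1291A>G	p.K431E	NA	24.2
17	18	44089726	rs571539488	LOXHD1	NM_001145473	c.169C>T	p.P57S	NA	25.6
7	18	44140215	rs759237437	LOXHD1	NM_144612	c.2891_2892insCTCATCAGAGGAGTCCTC	p.S964delinsSSSEESS	0.386	NA
1	14	74971538	rs760036288	LTBP2	NM_000428	c.4396G>A	p.G1466R	NA	32
15	14	74967643	NA	LTBP2	NM_000428	c.5410T>G	p.C1804G	NA	27.2
6	17	10426647	rs769778269	MYH2	NM_001100112	c.5555G>A	p.R1852Q	NA	33
11	17	10424643	rs34161789	MYH2	NM_001100112	c.5780G>A	p.R1927Q	0.854	35
17	10	95137125	rs367618675	MYOF	NM_133337	c.2024C>T	p.A675V	NA	22
11	10	95079636	rs146626145	MYOF	NM_133337	c.5552C>T	p.A1851V	0.248	23.8
3	6	32180684	rs150079294	NOTCH4	NM_004557	c.2443T>G	p.C815G	0.555	24.5
12	6	32163648	rs764118051	NOTCH4	NM_004557	c.5578C>A	p.R1860S	NA	34
9	20	47364384	NA	PREX1	NM_020820	c.253G>A	p.D85N	NA	23.2
11	20	47282854	rs149524742	PREX1	NM_020820	c.1705G>A	p.V569M	0.044	34
6	20	43945573	rs199904334	RBPJL	NM_001281449	c.1525A>C	p.N509H	NA	25.1
7	20	43942164	NA	RBPJL	NM_001281448	c.676G>C	p.V226L	NA	27.1
7	20	43942170	NA	RBPJL	NM_001281448	c.682A>C	p.T228P	NA	26
3	8	145736819	rs41555416	RECQL4	NM_004260	c.3622C>T	p.R1208C	0.500	23.5
13	8	145737142	rs61755067	RECQL4	NM_004260	c.3424G>C	p.D1142H	0.585	32
18	3	53126560	rs201230044	RFT1	NM_052859	c.1283G>A	p.S428N	NA	22
12	3	53126512	rs147740901	RFT1	NM_052859	c.1331C>T	p.T444M	0.588	22.7
17	9	135173569	NA	SETX	NM_001351527	c.5679G>A	p.M1893I	NA	25.1
12	9	135210039	rs527394446	SETX	NM_001351527	c.794A>G	p.D265G	0.659	28.5
17	16	89965023	rs144328773	TCF25	NM_014972	c.1081C>A	p.R361S	0.673	34
18	16	89972604	rs137901241	TCF25	NM_014972	c.1631G>A	p.R544Q	0.811	28.4
17	2	179554624	rs202234172	TTN	NM_133378	c.28031-1G>A	NA	0.360	26.1
15	2	179628969	rs139504522	TTN	NM_003319	c.9911C>T	p.P3304L	NA	23.6
13	2	179396568	rs201218828	TTN	NM_003319	c.77579A>C	p.E25860A	0.241	22.1
11	2	179411137	NA	TTN	NM_003319	c.67726G>A	p.G22576S	NA	23.3
14	9	132636952	rs142714756	USP20	NM_001008563	c.1838G>A	p.R613H	NA	32
12	9	132630423	rs148425010	USP20	NM_001008563	c.830G>A	p.S277N	0.379	23.2
10	5	82835589	rs146630369	VCAN	NM_001164097	c.3806T>C	p.L1269P	0.796	24.2
11	5	82850808	rs768896921	VCAN	NM_001126336	c.1463A>G	p.N488S	NA	28.9
13	14	75245347	NA	YLPM1	NM_019589	c.1072_1074del	p.358_358del	NA	NA
11	14	75265490	NA	YLPM1	NM_019589	c.3490C>G	p.R1164G	NA	25.5
17	3	102183076	rs375032047	ZPLD1	NM_175056	c.790C>T	p.R264X	0.603	48
15	3	102175036	NA	ZPLD1	NM_175056	c.376-1G>A	NA	NA	25.7
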