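# Transcribed reference table of rare variants segregating in two families
# (long format: one row per family x variant). homozygous_carrier flags a
# family in which one carrier was homozygous for the variant.
# case_control_p is the single-variant p-value looked up in a separately
# sequenced sporadic case-control cohort and is carried as annotation only.
family_id	chrom	pos	rsid	gene	accession	codon_change	protein_change	case_control_p	cadd_phred	homozygous_carrier
7	3	4716897	rs114719990	SETD2	NM_014159	c.3229A>G	p.T1077A	0.856	23.6	FALSE
14	3	4716897	rs114719990	SETD2	NM_014159	c.3229A>G	p.T1077A	0.856	23.6	FALSE
13	12	108105893	rs11547909	PWP1	NM_007062	c.1402G>A	p.E468K	0.801	24	FALSE
17	12	108105893	rs11547909	PWP1	NM_007062	c.1402G>A	p.E468K	0.801	24	FALSE
2	17	67013913	rs143651746	ABCA9	NM_080283	c.2785T>C	p.F929L	0.167	22.4	FALSE
16	17	67013913	rs143651746	ABCA9	NM_080283	c.2785T>C	p.F929L	0.167	22.4	FALSE
1	3	10413597	rs144118750	ATP2B2	NM_001683	c.1420G>A	p.V474I	0.092	21.8	FALSE
17	3	10413597	rs144118750	ATP2B2	NM_001683	c.1420G>A	p.V474I	0.092	21.8	FALSE
9	10	46122195	rs144142701	ZFAND4	NM_174890	c.1076T>A	p.L359H	0.592	26.1	FALSE
10	10	46122195	rs144142701	ZFAND4	NM_174890	c.1076T>A	p.L359H	0.592	26.1	FALSE
2	8	142487895	rs147691391	MROH5	NM_207414	c.1346A>T	p.E449V	0.273	24	FALSE
15	8	142487895	rs147691391	MROH5	NM_207414	c.1346A>T	p.E449V	0.273	24	FALSE
6	7	100365542	rs183014219	ZAN	NM_173059	c.4949C>A	p.T1650K	0.407	24.7	FALSE
17	7	100365542	rs183014219	ZAN	NM_173059	c.4949C>A	p.T1650K	0.407	24.7	FALSE
3	17	11459147	rs185956842	SHISA6	NM_001173461	c.890C>T	p.P297L	0.241	33	FALSE
13	17	11459147	rs185956842	SHISA6	NM_001173461	c.890C>T	p.P297L	0.241	33	FALSE
7	3	53326592	rs35988197	DCP1A	NM_018403	c.890C>G	p.A297G	0.278	24	FALSE
14	3	53326592	rs35988197	DCP1A	NM_018403	c.890C>G	p.A297G	0.278	24	FALSE
1	12	70949014	rs61758735	PTPRB	NM_001206971	c.4145C>T	p.T1382I	0.009	27.8	TRUE
2	12	70949014	rs61758735	PTPRB	NM_001206971	c.4145C>T	p.T1382I	0.009	27.8	FALSE
1	17	56833502	rs770124556	PPM1E	NM_014906	c.144_145insCCCGAA	p.E48delinsEPE	0.375	NA	FALSE
10	17	56833502	rs770124556	PPM1E	NM_014906	c.144_145insCCCGAA	p.E48delinsEPE	0.375	NA	FALSE
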