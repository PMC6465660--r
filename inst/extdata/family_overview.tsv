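# Transcribed reference cohort overview: 18 multiplex families analysed for
# segregating rare variants by exome sequencing; counts of genotyped members
# per three-state phenotype and of variants segregating in each family.
# reduced_penetrance marks the family whose pedigree suggested an unaffected
# obligate carrier (penetrance exemption).
family_id	n_affected	n_suggestive	n_unaffected	n_segregating	reduced_penetrance
1	2	3	0	75	FALSE
2	2	0	0	69	FALSE
3	1	3	2	36	FALSE
4	1	1	4	14	FALSE
5	1	2	4	3	FALSE
6	2	2	1	37	FALSE
7	1	2	3	17	FALSE
8	3	0	1	17	FALSE
9	2	0	2	12	FALSE
10	2	1	0	58	FALSE
11	2	1	0	79	FALSE
12	3	0	0	29	FALSE
13	2	0	0	71	FALSE
14	2	0	1	37	TRUE
15	2	0	0	60	FALSE
16	2	1	1	21	FALSE
17	1	1	0	124	FALSE
18	2	1	2	29	FALSE
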