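protein_id	avg_unique_reference	avg_unique_trap	swissprot	gene	protein_name	functional_class	trap_enriched_printed
Pa_6_2570	27.0	28.3	P38646	HSPA9	Stress-70 protein	Chaperones and Protein Import	FALSE
Pa_6_5750	16.7	13.7	P10809	HSPD1	60 kDa heat shock protein	Chaperones and Protein Import	FALSE
Pa_2_9700	14.3	15.3	O94826	TOMM70A	Mitochondrial import receptor subunit TOM70	Chaperones and Protein Import	FALSE
Pa_2_10580	9.0	9.3	O96008	TOMM40	Mitochondrial import receptor subunit TOM40	Chaperones and Protein Import	FALSE
Pa_6_1920	3.0	2.7	Q15388	TOMM20	Mitochondrial import receptor subunit TOM20	Chaperones and Protein Import	FALSE
Pa_2_12760	1.7	1.3	P35232	PHB	Prohibitin	Chaperones and Protein Import	FALSE
Pa_1_22300	12.0	15.3	P23378	GLDC	Glycine cleavage system P protein	Metabolism	FALSE
Pa_3_10790	11.3	13.0	O95571	ETHE1	Persulfide dioxygenase ETHE1	Metabolism	FALSE
Pa_5_5970	10.0	9.0	Q99798	ACO2	Aconitate hydratase	Metabolism	FALSE
Pa_3_11290	8.7	9.3	P00505	GOT2	Aspartate aminotransferase	Metabolism	FALSE
Pa_6_1590	8.0	7.0	P24752	ACAT1	Acetyl-CoA acetyltransferase	Metabolism	FALSE
Pa_3_6780	7.3	14.0	O75390	CS	Citrate synthase	Metabolism	TRUE
Pa_6_2730	7.3	6.3	P50213	IDH3A	Isocitrate dehydrogenase [NAD] subunit alpha	Metabolism	FALSE
Pa_3_2310	6.7	12.0	P10515	DLAT	Pyruvate dehydrogenase E2 component	Metabolism	TRUE
Pa_5_11920	5.7	5.0	Q13825	AUH	Methylglutaconyl-CoA hydratase	Metabolism	FALSE
Pa_2_1050	5.7	4.3	P78827	ilv-2	Ketol-acid reductoisomerase	Metabolism	FALSE
Pa_6_10000	5.0	3.7	C7C436	mcsA	2-methylcitrate synthase	Metabolism	FALSE
Pa_1_13140	4.7	6.3	P31327	CPS1	Carbamoyl-phosphate synthetase I (large chain/C-terminal region)	Metabolism	FALSE
Pa_3_7700	4.3	7.7	Q9P2R7	SUCLA2	Succinyl-CoA ligase subunit beta	Metabolism	TRUE
Pa_1_3450	4.0	6.0	Q92506	HSD17B8	Estradiol 17-beta-dehydrogenase 8	Metabolism	FALSE
Pa_1_17280	3.3	5.0	Q12428	PDH1	Probable 2-methylcitrate dehydratase	Metabolism	FALSE
Pa_1_14630	3.0	6.3	Q8N159	NAGS	N-acetylglutamate synthase	Metabolism	TRUE
Pa_4_7010	3.0	3.7	Q16698	DECR1	2.4-dienoyl-CoA reductase	Metabolism	FALSE
Pa_3_10910	3.0	3.3	P15937	acu-8	Acetyl-CoA hydrolase	Metabolism	FALSE
Pa_4_8600	3.0	3.0	O15382	BCAT2	Branched-chain-amino-acid aminotransferase	Metabolism	FALSE
Pa_2_6200	2.3	5.0	P23434	GCSH	Glycine cleavage system H protein	Metabolism	TRUE
Pa_6_8420	2.3	4.0	P45954	ACADSB	Short/branched chain specific acyl-CoA dehydrogenase	Metabolism	TRUE
Pa_2_430	2.3	3.3	Q9Y697	NFS1	Cysteine desulfurase	Metabolism	FALSE
Pa_3_2600	2.0	5.3	P40926	MDH2	Malate dehydrogenase	Metabolism	TRUE
Pa_1_15690	2.0	3.7	Q10341	cys2	Probable serine-O-acetyltransferase cys2	Metabolism	TRUE
Pa_2_4980	2.0	3.3	Q16836	HADH	Hydroxyacyl-coenzyme A dehydrogenase	Metabolism	TRUE
Pa_3_1420	2.0	2.0	Q9UHQ9	CYB5R1	NADH-cytochrome b5 reductase 1	Metabolism	FALSE
Pa_3_9430	1.7	3.0	P04181	OAT	Ornithine aminotransferase	Metabolism	TRUE
Pa_4_3040	1.7	1.7	P48735	IDH2	Isocitrate dehydrogenase [NADP]	Metabolism	FALSE
Pa_1_7660	1.7	1.3	Q02252	ALDH6A1	Methylmalonate-semialdehyde dehydrogenase	Metabolism	FALSE
Pa_7_10210	1.3	3.0	P30084	ECHS1	Enoyl-CoA hydratase	Metabolism	TRUE
Pa_1_1980	1.3	1.7	P51649	ALDH5A1	Succinate-semialdehyde dehydrogenase	Metabolism	FALSE
Pa_4_660	1.3	1.3	P34897	SHMT2	Serine hydroxymethyltransferase	Metabolism	FALSE
Pa_1_14370	2.7	2.3	O75947	ATP5H	ATP synthase subunit d	Electron Transport Chain and Respiration	FALSE
Pa_4_7160	2.0	4.7	O75489	NDUFS3	NADH dehydrogenase iron-sulfur protein 3	Electron Transport Chain and Respiration	TRUE
Pa_1_8620	2.0	1.7	O75306	NDUFS2	NADH dehydrogenase iron-sulfur protein 2	Electron Transport Chain and Respiration	FALSE
Pa_5_7500	1.3	1.7	O14561	NDUFAB1	Acyl carrier protein	Electron Transport Chain and Respiration	FALSE
Pa_6_240	1.3	1.3	P47985	UQCRFS1	Cytochrome b-c1 complex subunit Rieske	Electron Transport Chain and Respiration	FALSE
Pa_2_12010	8.7	10.0	P49411	TUFM	Mitochondrial elongation factor Tu	Other Pathways	FALSE
Pa_4_1130	2.3	2.3	nhd			Other Pathways	FALSE
Pa_5_8240	2.0	2.7	P30044	PRDX5	Peroxiredoxin-5	Other Pathways	FALSE
Pa_6_8740	2.0	2.3	P10599	TXN	Thioredoxin	Other Pathways	FALSE
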