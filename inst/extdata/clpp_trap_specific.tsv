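protein_id	avg_unique_trap	printed_ef	swissprot	gene	protein_name	functional_class
Pa_6_5510	7.3		Q8NBU5	ATAD1	ATPase family AAA domain-containing protein 1	Chaperones
Pa_6_5590	3.7		O76031	CLPX	ATP-dependent Clp protease ATP-binding subunit clpX-like	Chaperones
Pa_6_5560	15.7		Q02218	OGDH	2-oxoglutarate dehydrogenase E1 component	Metabolism
Pa_6_1640	7.7		P31327	CPS1	Carbamoyl-phosphate synthetase I (small chain/N-terminal region)	Metabolism
Pa_7_9520	7.3		O00330	PDHX	Pyruvate dehydrogenase protein X component	Metabolism
Pa_5_5370	5.0	3.8	P36957	DLST	2-oxoglutarate dehydrogenase E2 component	Metabolism
Pa_7_10050	4.0		P08559	PDHA1	Pyruvate dehydrogenase E1 component subunit alpha	Metabolism
Pa_1_13750	2.7		P48728	AMT	Aminomethyltransferase	Metabolism
Pa_5_5810	2.3		P09622	DLD	Dihydrolipoyl dehydrogenase	Metabolism
Pa_1_15800	2.0		P11177	PDHB	Pyruvate dehydrogenase E1 component subunit beta	Metabolism
Pa_1_20100	1.3		P26440	IVD	Isovaleryl-CoA dehydrogenase	Metabolism
Pa_3_9520	1.3		P35914	HMGCL	Hydroxymethylglutaryl-CoA lyase	Metabolism
Pa_3_4870	21.0		P28331	NDUFS1	NADH dehydrogenase 75 kDa subunit	Electron Transport Chain
Pa_4_7950	3.7		P49821	NDUFV1	NADH dehydrogenase flavoprotein 1	Electron Transport Chain
Pa_5_9670	3.3		Q5T2R2	PDSS1	Decaprenyl-diphosphate synthase subunit 1	Electron Transport Chain
Pa_3_11170	10.7	4.0	O59778	bio2	Biotin synthase	Other Pathways
Pa_1_18430	2.7		P22626	HNRNPA2B1	Heterogeneous nuclear ribonucleoproteins A2/B1	Other Pathways
Pa_2_10680	2.0		Q86SX6	GLRX5	Glutaredoxin-related protein 5	Other Pathways
Pa_1_6330	1.7		Q96RP9	GFM1	Mitochondrial elongation factor G	Other Pathways
Pa_5_2590	1.7		G2TRP3	ymr31	Mitochondrial 37S ribosomal protein YMR-31	Other Pathways
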