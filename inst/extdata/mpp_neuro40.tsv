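gene_symbol	protein_name	log2fc	significant	direction
ACADVL	Very long-chain specific acyl-CoA dehydrogenase, mitochondrial	1.562	TRUE	↑
ACAT1	Acetyl-CoA acetyltransferase, mitochondrial	4.168	TRUE	↑
ALCAMA	CD166 antigen homolog A	2.412	TRUE	↑
ATP2A2A	Calcium-transporting ATPase	-2.398	TRUE	↓
ATP2B1A	Calcium-transporting ATPase	-2.477	TRUE	↓
ATP2B4	ATPase, Ca++ transporting, plasma membrane 4	-1.882	TRUE	↓
ATP5MJ	6.8 kDa mitochondrial proteolipid-like	2.322	TRUE	↑
ATP5PD	ATP synthase subunit d, mitochondrial	1.499	TRUE	↑
CAMK2B1	calcium/calmodulin-dependent protein kinase	-1.503	TRUE	↓
CAPN2L	Calpain-2 catalytic subunit	-5.777	TRUE	↓
CKMT2B	Creatine kinase S-type, mitochondrial	1.477	TRUE	↑
CS	Citrate synthase, mitochondrial	-1.614	TRUE	↓
DLST	Dihydrolipoyllysine-residue succinyltransferase component of 2-oxoglutarate dehydrogenase complex, mitochondrial	-1.652	TRUE	↓
DMGDH	Dimethylglycine dehydrogenase, mitochondrial	-3.745	TRUE	↓
DNAH2	Dynein axonemal heavy chain 2 isoform X1	2.464	TRUE	↑
FDX1	Adrenodoxin, mitochondrial	1.468	TRUE	↑
ICN2	Protein S100	-1.669	TRUE	↓
INAB	Internexin neuronal intermediate filament protein, alpha b	-1.694	TRUE	↓
LONP1	Lon protease homolog, mitochondrial	1.827	TRUE	↑
NDUFS6	NADH dehydrogenase [ubiquinone] iron-sulfur protein 6, mitochondrial	1.77	TRUE	↑
NEFMB	Neurofilament medium chain b	-2.489	TRUE	↓
PARK7	Parkinson disease protein 7 homolog	1.946	TRUE	↑
PRDX3	Thioredoxin-dependent peroxide reductase, mitochondrial	-1.548	TRUE	↓
PSMA8	Proteasome subunit alpha type	2.005	TRUE	↑
PSMB10	Proteasome subunit beta	3.793	TRUE	↑
PSMB3	Proteasome subunit beta	2.26	TRUE	↑
PSMB5	Proteasome subunit beta	3.372	TRUE	↑
PSMC1B	Proteasome	2.198	TRUE	↑
PSMC5	26S proteasome regulatory subunit 8	-3.234	TRUE	↓
PSMD11B	26S proteasome non-ATPase regulatory subunit 11B	1.633	TRUE	↑
SDHA	Succinate dehydrogenase [ubiquinone] flavoprotein subunit, mitochondrial	-2.272	TRUE	↓
SI:CH211-125O16.4	Neuroblast differentiation-associated protein AHNAK	-1.567	TRUE	↓
SLC25A11	Mitochondrial 2-oxoglutarate/malate carrier protein	-2.773	TRUE	↓
SLC25A3B	Solute carrier family 25 member 3	-2.134	TRUE	↓
STIP1	Stress-induced-phosphoprotein 1	-1.573	TRUE	↓
TOMM7	Mitochondrial import receptor subunit TOM7 homolog	1.909	TRUE	↑
UQCRC1	Cytochrome b-c1 complex subunit 1, mitochondrial	2.115	TRUE	↑
UQCRFS1	Cytochrome b-c1 complex subunit Rieske, mitochondrial	-1.516	TRUE	↓
VAMP2	Vesicle-associated membrane protein 2	-4.728	TRUE	↓
VAPB	Vesicle-associated membrane protein-associated protein B/C isoform X1	3.207	TRUE	↑
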