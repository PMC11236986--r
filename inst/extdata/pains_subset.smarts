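# Curated subset of published pan-assay interference (PAINS) substructure
# families, written as SMARTS. One pattern per line: id <TAB> SMARTS.
# This is a representative subset covering the most frequently matched
# families (quinones, catechols, rhodanines, azo dyes, hydrazones, Michael
# acceptors), not the full published catalog.
quinone_para	O=C1C=CC(=O)C=C1
quinone_ortho	O=C1C(=O)C=CC=C1
catechol	Oc1ccccc1O
hydroquinone	Oc1ccc(O)cc1
rhodanine	O=C1CSC(=S)N1
ene_rhodanine	C=C1SC(=S)NC1=O
thiourea	NC(=S)N
azo_aryl	cN=Nc
hydrazone_aryl	cC=NN
ene_one_ene	C=CC(=O)C=C
alkylidene_barbiturate	C=C1C(=O)NC(=O)NC1=O
imine_phenol	Oc1ccccc1C=N
acyl_hydrazone	O=CNN=C
acrylonitrile	C=CC#N
isothiazolone	O=C1C=CSN1
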