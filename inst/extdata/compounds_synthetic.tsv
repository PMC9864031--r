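id	name	smiles
AMG1	synthetic glutamine mimic (antimetabolite candidate)	C(CC(=O)N)C(C(=O)O)N
DON	6-diazo-5-oxo-L-norleucine	C(CC(=O)C=[N+]=[N-])C(C(=O)O)N
MEGLUTOL	meglutol (3-hydroxy-3-methylglutarate)	CC(CC(=O)O)(CC(=O)O)O
PHYTOSPH	phytosphingosine	CCCCCCCCCCCCCCC(C(C(CO)N)O)O
ASPIRIN	acetylsalicylic acid (decoy)	CC(=O)OC1=CC=CC=C1C(=O)O
CAFFEINE	caffeine (decoy)	CN1C=NC2=C1C(=O)N(C(=O)N2C)C
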