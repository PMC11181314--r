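name	smarts
rhodanine	[#16]1[#6](=[#16])[#7][#6](=O)[#6]1
ene_rhodanine	[#6]=[#6]1[#16][#6](=[#16])[#7][#6]1=O
hydroxyphenyl_hydrazone_para	[OX2H]c1ccc(cc1)[#6X3]=[NX2][NX3]
hydroxyphenyl_hydrazone_ortho	[OX2H]c1ccccc1[#6X3]=[NX2][NX3]
catechol	[OX2H]c1ccccc1[OX2H]
para_quinone	O=C1C=CC(=O)C=C1
ortho_quinone	O=C1C(=O)C=CC=C1
alkylidene_barbiturate	[#6]=[#6]1[#6](=O)[#7][#6](=O)[#7][#6]1=O
isothiazolone	[#8]=[#6]1[#6]~[#6]~[#16]~[#7]1
azo_aryl	c[NX2]=[NX2]c
ene_hydantoin	[#6]=[#6]1[#6](=O)[#7][#6](=O)[#7]1
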