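pathway_type	chemicals	enzymes
Carbohydrate metabolism	399	274
Energy metabolism	153	102
Lipid metabolism	405	337
Nucleotide metabolism	135	113
Amino acid metabolism	427	215
Metabolism of other amino acids	132	106
Glycan biosynthesis and metabolism	22	156
Metabolism of cofactors and vitamins	303	175
Metabolism of terpenoids and polyketides	195	46
Biosynthesis of other secondary metabolites	326	54
Xenobiotics biodegradation and metabolism	422	141
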