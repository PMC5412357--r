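name	anticodon	arm_map	length	sequence	structure
trnI	GAT	standard	73	TCGTTGGTATATCATTCAATAGATAATAATCTTGATAAGATTAATAGTGATAGCTGGAATCTATCCCAACGAA	(((((((..((((........)))).(((((.......))))).....(((((.......)))))))))))).
trnQ	TTG	standard	73	GGTATTTTAATAAATATCTGTTTATAGGTAGTTTTGAACTACCGTGTGTCTTTATTTGGGAAAGAAAATACCA	(((((((..((((........)))).(((((.......))))).....(((((.......)))))))))))).
trnM	CAT	standard	73	TGACTTTTATATAACTATTTTTATAAAAATTTTCATAAAATTTATGGTGGTAGTTAACTTCTACCAAAGTCAA	(((((((..((((........)))).(((((.......))))).....(((((.......)))))))))))).
trnW	TCA	standard	73	ATAAATATAACGCAAGTGAAAGCGTAGATTTTTTCAAAAAATCATAATTATACATTGTTAGTATATATTTATA	(((((((..((((........)))).(((((.......))))).....(((((.......)))))))))))).
trnC	GCA	standard	73	TCTCGTTTACAGTAGACAAAGACTGATATTCTTGCAAAGAATAATAAGGTAAATAATTATTTTACAACGAGAA	(((((((..((((........)))).(((((.......))))).....(((((.......)))))))))))).
trnY	GTA	standard	73	TAGCCTATAAAAATTACTTATTTTTAACGTGTTGTAAACACGTTCATTAACCATTCCTTTTGGTTTAGGCTAA	(((((((..((((........)))).(((((.......))))).....(((((.......)))))))))))).
trnL2	TAA	standard	73	TAGTCGTTAAAACCTTCAGCAGTTTAGACTTTTTAAAAAAGTCATATCCAATTAGATTGTAATTGACGACTAA	(((((((..((((........)))).(((((.......))))).....(((((.......)))))))))))).
trnK	CTT	standard	73	GATTCGATAGAAGGACCAAGGCTTCATTCATTTCTTAAATGAAAATAATTTTTAAGTTTTAAAAATCGAATCA	(((((((..((((........)))).(((((.......))))).....(((((.......)))))))))))).
trnD	GTC	standard	73	TTTAACCTATGCGGTTAATGCCGCAAATAATTTGTCAAATTATTGTCAATTCGAACTTTGCGAATGGTTAAAA	(((((((..((((........)))).(((((.......))))).....(((((.......)))))))))))).
trnG	TCC	standard	73	AATAAAATATTAGACGACTTACTAAATGACCTTTCCAAGGTCAAATAATCTGCGTGAGAAGCAGATTTTATTA	(((((((..((((........)))).(((((.......))))).....(((((.......)))))))))))).
trnA	TGC	standard	73	TATCAGATAAAACTTATTTATGTTTATATATTTTGCAAATATAAAGTTGTGACTATGATTGTCACTCTGATAA	(((((((..((((........)))).(((((.......))))).....(((((.......)))))))))))).
trnR	TCG	standard	73	ATATAATTAACTGTAGGTGAACAGTAATATTTTTCGAAAATATTAATTCTTATTATGTGCATAAGATTATATA	(((((((..((((........)))).(((((.......))))).....(((((.......)))))))))))).
trnN	GTT	standard	73	AGTGAACTATATCACGGTTAAGATAATAGACTTGTTAAGTCTATGCTAAAATTCAATAGGAATTTGTTCACTA	(((((((..((((........)))).(((((.......))))).....(((((.......)))))))))))).
trnS1	GCT	noDHU	62	AACATTTTATTCAAAGTGGTTTGCTAAACCACTTCATTTCAGACATCTTCTGAAAAATGTTA	(((((((........(((((.......))))).....(((((.......)))))))))))).
trnE	TTC	standard	73	AAATTAATAATAAATTTTTAATTATACATTATTTTCAATAATGATGTTATAACTTTGAACGTTATTTAATTTA	(((((((..((((........)))).(((((.......))))).....(((((.......)))))))))))).
trnF	GAA	standard	73	TTCTGGATAACGTTTAATAAGACGTAAGTGATTGAAAATCACTATTCGTCCTATTCATATTAGGATCCAGAAA	(((((((..((((........)))).(((((.......))))).....(((((.......)))))))))))).
trnH	GTG	standard	73	AGAAGATTACAATAATGTATCATTGATATTGTTGTGAACAATAGGTGACAGATCGTCTTTATCTGATCTTCTA	(((((((..((((........)))).(((((.......))))).....(((((.......)))))))))))).
trnT	TGT	standard	73	CAGCTCTTATATTGAAACGTAAATAACCCAGTTTGTAACTGGGTCCGTAAGCCAATTAAAGGCTTAGAGCTGA	(((((((..((((........)))).(((((.......))))).....(((((.......)))))))))))).
trnP	TGG	standard	73	CCTTTCTTAACCATTTAGTGGTGGTATGATGTTTGGAACATCAACGACAAATTATTTATAAATTTAGAAAGGA	(((((((..((((........)))).(((((.......))))).....(((((.......)))))))))))).
trnS2	TGA	standard	73	ATGAAATTAGAATATACTCTAATTCACATTATTTGAAATAATGTAAAATCGCATTATCACTGCGAATTTCATA	(((((((..((((........)))).(((((.......))))).....(((((.......)))))))))))).
trnL1	TAG	standard	73	GTTCACTTAAGAATAAGAAGTTTCTAATAAATTTAGAATTTATGTTCTACAAATAAATAATTTGTAGTGAACA	(((((((..((((........)))).(((((.......))))).....(((((.......)))))))))))).
trnV	TAC	standard	73	ACACGAATAATATATTATCTCATATACAGAATTTACAATTCTGTATCGGGGACTTGTATAGTCCCTTCGTGTA	(((((((..((((........)))).(((((.......))))).....(((((.......)))))))))))).
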