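species	item	sequence	start	end
PT	Domain1		1	279
TM	Domain1		1	280
PT	TAS	ACGCAATGCATATATGTATTAACACCATTGTTTTATATTAAACAT	23	67
TM	TAS	ACGCAATGCATATATGTATTATCACCATTATTTTATATCAAACAT	23	67
PT	Domain2		280	637
TM	Domain2		281	637
PT	CSB-F	ATGTAGTAAGAGCCCACC	280	297
TM	CSB-F	ATGTAGTAAGAGCCCACC	281	298
PT	CSB-E	AGCGTGTGGGGGGT	502	515
TM	CSB-E	AGAGTGTGGCGGGT	503	516
PT	OH	CTTTTTTTTTTTCCTTTCACTTGACATCTCAGAGTG	519	554
TM	OH	TTTTTTTTTTTTCCTTTCATTTGACATCCCAGAGTG	520	555
PT	Domain3		638	892
TM	Domain3		638	893
PT	CSB1	ATTGCATAACTGATATCATGAGCATA	638	663
TM	CSB1	ATTGCATAACTGATATCATGAGCATA	638	663
PT	CSB2	AAACCCCCCCTACCCCC	728	744
TM	CSB2	AAACCCCCCCTACCCCC	728	744
PT	CSB3	TGTAAACCCCCCGGAAACAG	773	792
TM	CSB3	TGCAAACCCCCCGGAAACAG	773	792
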