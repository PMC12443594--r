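bg1	1000	1999	GENE_A	0	+
bg1	3000	3999	GENE_B	0	+
bg1	5000	5999	GENE_C	0	-
bg1	8000	8999	GENE_D	0	+
bg2	1500	2499	GENE_E	0	-
bg2	4000	4999	GENE_F	0	+
bg2	9000	9999	GENE_G	0	+
bg1	12000	12999	GENE_H	0	-
bg2	15000	15999	GENE_I	0	+
bg1	20000	20999	GENE_J	0	+
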