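direction	errors	mwt	edge	pam	ttest	wilcoxon
up	0	1628	1109	938	1087	1054
up	1	0	202	211	184	187
up	2	0	27	73	20	14
up	3	0	1	25	0	0
up	4	0	0	6	0	0
up	9	0	0	1	0	0
down	8	0	0	1	0	0
down	7	0	0	1	0	0
down	6	0	0	2	0	0
down	5	0	0	12	0	0
down	4	0	3	29	2	2
down	3	0	16	67	15	10
down	2	0	64	118	68	64
down	1	0	317	314	343	372
down	0	1201	1090	1031	1110	1126
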