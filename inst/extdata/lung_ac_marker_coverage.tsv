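gene	n_supporting_refs	ecd_default	ecd_extended	edge
ATP10B	1	YES	YES	NO
AURKA	2	YES	YES	YES
CLDN5	1	YES	YES	YES
COL11A1	2	YES	YES	YES
DNAI2	1	NO	YES	NO
FABP6	1	NO	NO	NO
HIGD1B	1	YES	YES	YES
ILF3	3	YES	YES	NO
IQCG	1	NO	NO	NO
LRRC48	1	NO	NO	NO
LRRC50	1	NO	NO	NO
MCM6	2	YES	YES	NO
MUC4	2	NO	YES	NO
RARRES2	2	YES	YES	YES
RFTN1	4	YES	YES	NO
SCG5	1	YES	YES	NO
SCGB1A1	2	NO	YES	YES
SFTPA2	1	YES	YES	NO
SFTPB	1	NO	YES	NO
SFTPC	1	YES	YES	YES
TFPI2	1	YES	YES	YES
TM4SF4	1	NO	YES	NO
TOP2A	3	YES	YES	YES
XAGE1A	2	YES	YES	YES
XAGE1B	4	no_probe	no_probe	no_probe
XAGE1C	2	no_probe	no_probe	no_probe
XAGE1D	2	no_probe	no_probe	no_probe
XAGE1E	2	no_probe	no_probe	no_probe
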