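probe_id	chromosome	position	gene_names	gene_regions	cpg_context	delta_adipose	delta_leukocyte
cg02379560	4	40859280	APBB2;APBB2;APBB2;APBB2;APBB2;APBB2;APBB2	Body;TSS200;TSS200;Body;TSS200;Body;TSS200	S_Shore	-0.11	-0.07
cg20251225	1	1609551	CDK11B;CDK11B;CDK11B;CDK11B;CDK11B;LOC728661;CDK11B	Body;Body;Body;Body;Body;5'UTR;5'UTR	S_Shore	-0.10	-0.06
cg15681239	3	38080203	DLEC1;DLEC1	TSS1500;TSS1500	N_Shore	-0.11	-0.06
cg25932599	4	1005201	FGFRL1;FGFRL1;FGFRL1	TSS1500;TSS1500;TSS1500	Island	-0.12	-0.11
cg15644324	1	42384647	HIVEP3;HIVEP3	TSS200;TSS200	S_Shore	0.13	0.07
cg00514575	5	180231155	MGAT1;MGAT1;MGAT1;MGAT1;MGAT1	TSS1500;5'UTR;TSS1500;5'UTR;TSS1500	S_Shore	-0.12	-0.06
cg11201447	8	128808063	MIR1204;PVT1	TSS200;Body	S_Shore	-0.10	-0.06
cg25152348	22	50946712	NCAPH2;LMF2;NCAPH2;NCAPH2;NCAPH2	1stExon;TSS1500;5'UTR;5'UTR;1stExon	Island	-0.10	-0.13
cg06936779	1	151171405	PIP5K1A;PIP5K1A;PIP5K1A;PIP5K1A;PIP5K1A;PIP5K1A;PIP5K1A;PIP5K1A	5'UTR;1stExon;5'UTR;1stExon;5'UTR;1stExon;1stExon;5'UTR	Island	-0.12	-0.09
cg18437077	7	100860918	PLOD3;PLOD3;ZNHIT1	1stExon;5'UTR;TSS200	Island	-0.11	-0.06
cg22712983	2	219187374	PNKD;PNKD	TSS1500;Body	N_Shore	0.12	0.10
cg02051077	7	131241343	PODXL;PODXL;PODXL;PODXL	5'UTR;1stExon;5'UTR;1stExon	Island	-0.11	-0.07
cg11381564	6	32808619	PSMB8;PSMB8	3'UTR;3'UTR	S_Shore	-0.14	-0.08
cg14010720	20	62168878	PTK6	TSS200	S_Shore	-0.13	-0.06
cg10542975	11	67205096	PTPRCAP;PTPRCAP	5'UTR;1stExon	S_Shore	-0.15	-0.06
cg02874908	11	67205113	PTPRCAP;PTPRCAP	5'UTR;1stExon	S_Shore	-0.12	-0.09
cg17858911	12	123012351	RSRC2;RSRC2;RSRC2;KNTC1	TSS1500;TSS1500;TSS1500;5'UTR	S_Shore	-0.12	-0.11
cg02996471	19	3178512	S1PR4	TSS1500	N_Shore	-0.12	-0.06
cg07496545	5	140683737	SLC25A2	TSS200	Island	0.12	0.05
cg07576222	15	67357975	SMAD3	TSS1500	Island	-0.11	-0.07
cg13104938	11	843956	TSPAN4;TSPAN4;TSPAN4;TSPAN4;TSPAN4;POLR2L;TSPAN4;TSPAN4	TSS1500;5'UTR;TSS200;5'UTR;5'UTR;TSS1500;5'UTR;5'UTR	S_Shore	0.11	0.06
cg23713156	17	80606235	WDR45L;WDR45L	5'UTR;1stExon	Island	-0.10	-0.09
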