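gene	chrom	pos	ref	alt	label
KRAS	2	20000500	G	A	G12D
GNAS	3	70000500	C	T	R201C
TP53	4	10000500	C	T	hotspot
SMAD4	4	18000500	G	T	hotspot
CDKN2A	2	60000500	C	A	hotspot
BRAF	2	30000500	T	A	hotspot
PIK3CA	2	38000500	G	A	hotspot
MAP2K4	1	20000500	C	G	hotspot
TGFBR1	4	24000500	A	G	hotspot
TGFBR2	4	28000500	C	T	hotspot
RNF43	3	10000500	G	A	hotspot
CTNNB1	3	20000500	T	C	hotspot
STK11	1	30000500	C	T	hotspot
ARID1A	1	8000500	G	A	hotspot
KDM6A	4	32000500	A	T	hotspot
SF3B1	3	30000500	A	G	hotspot
RBM10	4	40000500	G	C	hotspot
IDH1	4	46000500	C	T	hotspot
PTEN	4	52000500	A	C	hotspot
APC	4	58000500	C	T	hotspot
ATM	3	80000500	G	T	hotspot
BRCA1	4	64000500	T	G	hotspot
BRCA2	4	70000500	A	G	hotspot
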