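name	pattern	category
ABRE	ACGTG	ABA responsiveness
ABRE-like	TACGTGTC	ABA responsiveness
motif-IIb	CCGCCGCGCT	ABA responsiveness
CE3	GACGCGTGTC	ABA responsiveness
TCA-element	CCATCTTTTT	salicylic acid responsiveness
CA-element	CCAACTC	salicylic acid responsiveness
CGTCA-motif	CGTCA	MeJA responsiveness
TGACG-motif	TGACG	MeJA responsiveness
ERE	ATTTCAAA	ethylene responsiveness
AuxRR-core	GGTCCAT	auxin responsiveness
TGA-element	AACGAC	auxin responsiveness
P-box	CCTTTTG	gibberellin responsiveness
TATC-box	TATCCCA	gibberellin responsiveness
GARE-motif	TCTGTTG	gibberellin responsiveness
LTR	CCGAAA	low-temperature responsiveness
HSE	AAAAAATTTC	heat stress responsiveness
TC-rich_repeats	ATTTTCTTCA	defence and stress responsiveness
WUN-motif	AAATTTCCT	wound responsiveness
W-box	TTGACC	WRKY binding, defence
Skn-1_motif	GTCAT	endosperm expression
GCN4_motif	TGAGTCA	endosperm expression
RY-element	CATGCATG	seed-specific regulation
as-1	TGACGTCA	root-specific / oxidative stress
motif-I	CAGTTA	root-specific expression
HD-Zip1	CAATWATTG	differentiation of palisade mesophyll cells
HD-Zip2	GCATTAAT	leaf morphology development
MRE	AACCTAA	MYB binding, light responsiveness
MBS	CAACTG	MYB binding, drought inducibility
ACE	CTAACGTATT	light responsiveness
Box-4	ATTAAT	light responsiveness
Box-I	TTTCAAA	light responsiveness
G-box	CACGTG	light responsiveness
GT1-motif	GGTTAA	light responsiveness
I-box	GATAAGRNR	light responsiveness
Sp1	GGGCGG	light responsiveness
GATA-motif	AAGGATAAGG	light responsiveness
CAT-box	GCCACT	meristem expression
circadian	CAANNNNATC	circadian control
O2-site	GATGAYRTGR	zein metabolism regulation
A-box	CCGTCC	elicitor-responsive
E-box	CANNTG	bHLH binding
GCGGCG-consensus	GCGGCG	LOB-domain protein binding
de-novo-example	GGTTGAATACAC	de novo discovered promoter motif (synthetic example)
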