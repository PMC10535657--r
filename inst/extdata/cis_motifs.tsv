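# Curated plant cis-regulatory element consensus motifs (IUPAC).
# Columns: name, pattern, category.
name	pattern	category
G-Box	CACGTG	light
Box 4	ATTAAT	light
GT1-motif	GGTTAA	light
TCT-motif	TCTTAC	light
I-box	GATAAG	light
MRE	AACCTAA	light
AE-box	AGAAACAA	light
ABRE	TACGTGTC	hormone
CGTCA-motif	CGTCA	hormone
TGACG-motif	TGACG	hormone
TCA-element	CCATCTTTTT	hormone
GARE-motif	TCTGTTG	hormone
P-box	CCTTTTG	hormone
TATC-box	TATCCCA	hormone
AuxRR-core	GGTCCAT	hormone
TGA-element	AACGAC	hormone
SARE	TTCGACCATCTT	hormone
CAT-box	GCCACT	development
O2-site	GATGAYRTGR	development
GCN4_motif	TGAGTCA	development
HD-Zip 1	CAATWATTG	development
HD-Zip 3	GTAATSATTAC	development
LTR	CCGAAA	environment
MBS	CAACTG	environment
ARE	AAACCA	environment
TC-rich repeats	ATTCTCTAAC	environment
GC-motif	CCCCCG	environment
WUN-motif	AAATTTCCT	environment
CAAT-box	CCAAT	promoter/binding
TATA-box	TATAAA	promoter/binding
W-box	YTGACY	promoter/binding
A-box	CCGTCC	promoter/binding
MYB	TAACCA	unknown
MYC	CATGTG	unknown
STRE	AGGGG	unknown
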