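# Published Ka, Ks, Ka/Ks and divergence times for duplicated bilberry
# (Vaccinium myrtillus) VmWRKY gene pairs. time_mya "-" entries are
# undefined; rows with note "**" were computed with a different program
# (KaKs_Calculator2.0) and are excluded from internal consistency checks.
pair	ka	ks	ka_ks	type	time_mya	note
VmWRKY37/VmWRKY38	NaN	NaN	NaN	tandem	NA
VmWRKY40/VmWRKY41	0.0018229	0.0116	0.1571441	tandem	0.138938872
VmWRKY46/VmWRKY47	NaN	NaN	NaN	tandem	NA
VmWRKY48/VmWRKY49	0.2153629	0.4347175	0.4954089	tandem	16.41485794
VmWRKY4/VmWRKY19	0.1863388	1.2026591	0.154939	segmental	14.20264977
VmWRKY65/VmWRKY24	0.0117773	0.1173245	0.1003819	segmental	0.897657317
VmWRKY11/VmWRKY44	0.1737659	0.7309832	0.2377154	segmental	13.24435556
VmWRKY14/VmWRKY32	3.34641	4.13312	0.80965	segmental	3.5265	**
VmWRKY61/VmWRKY63	1.0942903	1.7098092	0.6400073	segmental	83.40627188
VmWRKY59/VmWRKY28	NaN	NaN	NaN	segmental	NA
VmWRKY67/VmWRKY22	0.9085855	NaN	NaN	segmental	69.25193994
VmWRKY13/VmWRKY25	NaN	NaN	NaN	segmental	NA
VmWRKY62/VmWRKY55	NaN	NaN	NaN	segmental	NA
VmWRKY2/VmWRKY16	NaN	NaN	NaN	segmental	NA
VmWRKY1/VmWRKY3	0.006383	0.0427162	0.1494286	segmental	0.486510442
VmWRKY58/VmWRKY29	0	NaN	NaN	segmental	0
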