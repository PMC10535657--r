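# Published gene table for the 69 characterized bilberry (Vaccinium
# myrtillus) VmWRKY genes: genomic coordinates, family group, CDS and
# protein lengths, and ProtParam-style physicochemical properties.
# The VmWRKY23 row's CDS/aa pair violates the coding-length relation
# (published erratum; flagged, not corrected).
identifier	gene	group	chr	start	end	strand	cds_nt	aa	mw	pi	instability	gravy
Vmy01g15360	VmWRKY1	I	Chr1	562585	565972	+	2028	675	73184.1101	5.8614	57.63496	-0.78104
Vmy01g15494	VmWRKY2	I	Chr1	1805033	1810979	-	1704	567	61989.0022	6.7926	52.19947	-0.75467
Vmy01g15496	VmWRKY3	I	Chr1	1815400	1821385	-	1356	451	48425.053	4.7083	62.64989	-0.84169
Vmy01g16077	VmWRKY4	IIb	Chr1	8788109	8792213	+	1617	538	58725.4997	6.5958	45.7948	-0.70985
Vmy01g17102	VmWRKY5	I	Chr1	26099661	26103183	+	1425	474	51364.8663	8.9407	45.66751	-0.80696
Vmy01g17169	VmWRKY6	IIc	Chr1	27189670	27191923	-	876	291	32429.5196	5.0955	58.33574	-0.73814
Vmy01g18042	VmWRKY7	IIc	Chr1	39683976	39685598	+	1017	338	37888.7482	5.9652	61.04822	-0.88817
Vmy02g31145	VmWRKY8	IIc	Chr2	25519147	25521976	+	876	291	32444.1819	6.4528	70.26117	-1.01993
Vmy02g31720	VmWRKY9	I	Chr2	32825778	32832842	+	1611	536	58052.007	6.6116	58.72351	-0.81287
Vmy02g32314	VmWRKY10	IIb	Chr2	39960782	39963444	+	1578	525	57472.7052	5.2647	48.67124	-0.84019
Vmy03g6652	VmWRKY11	IIa	Chr3	3347599	3349848	+	1008	335	37183.4869	7.5707	54.8606	-0.66806
Vmy03g7279	VmWRKY12	IIc	Chr3	10749229	10756210	-	807	268	29564.1446	5.4622	62.2306	-0.84179
Vmy03g7725	VmWRKY13	IIc	Chr3	17418681	17421414	-	537	178	20532.6635	9.6275	33.60225	-1.04831
Vmy03g7865	VmWRKY14	IIe	Chr3	20460927	20465147	-	867	287	32027.1993	5.1769	64.9216	-0.81986
Vmy03g9094	VmWRKY15	IIc	Chr3	37596334	37598020	+	906	301	33881.2384	5.6614	65.33953	-0.84153
Vmy04g26811	VmWRKY16	I	Chr4	2341763	2347090	-	1782	593	64536.4045	6.4074	51.08398	-0.73693
Vmy04g26879	VmWRKY17	IIb	Chr4	2979626	2984279	+	1467	488	53622.5498	9.0454	59.18258	-0.72992
Vmy04g27403	VmWRKY18	I	Chr4	8533619	8536143	-	1437	478	52408.7018	6.7441	55.2864	-1.03536
Vmy04g27528	VmWRKY19	IIb	Chr4	10145599	10147984	+	1575	524	57082.0727	6.3267	45.18626	-0.71164
Vmy04g27619	VmWRKY20	IIe	Chr4	11366863	11367486	-	624	207	23294.8101	6.5994	60.09614	-0.81063
Vmy04g28682	VmWRKY21	IIc	Chr4	30876942	30884972	-	843	280	31697.0249	6.3051	53.21964	-0.76571
Vmy04g28697	VmWRKY22	IIc	Chr4	31197907	31202208	+	564	187	21115.9108	5.7896	58.50588	-0.97701
Vmy04g29204	VmWRKY23	I	Chr4	38844924	38855142	+	384	513	56570.0032	5.5428	53.90975	-0.86667
Vmy05g13713	VmWRKY24	IIb	Chr5	34491956	34498576	-	1734	577	63130.9269	6.6639	50.274	-0.78943
Vmy05g14091	VmWRKY25	IIc	Chr5	38520966	38524762	-	396	131	15231.1171	9.7211	37.99313	-1.08397
Vmy06g33434	VmWRKY26	IIc	Chr6	535034	539542	-	798	265	29556.1168	9.1886	62.50906	-0.74113
Vmy06g33447	VmWRKY27	IIe	Chr6	641618	643258	-	978	325	37054.0126	4.6838	76.58988	-1.212
Vmy06g34052	VmWRKY28	IId	Chr6	6251528	6262173	-	1512	503	57035.1503	9.8303	46.33002	-0.57475
Vmy06g34072	VmWRKY29	I	Chr6	6434377	6437276	+	1716	571	62463.3081	7.7103	65.48984	-0.9387
Vmy06g34731	VmWRKY30	IIe	Chr6	14371009	14374552	-	1452	483	52681.3465	5.6884	53.77598	-0.87433
Vmy06g35042	VmWRKY31	IIb	Chr6	18292323	18295336	+	1761	586	63759.1384	6.3526	49.9041	-0.69369
Vmy06g35510	VmWRKY32	IIe	Chr6	25953649	25954811	+	816	271	30225.875	5.2132	58.61476	-0.86236
Vmy07g24811	VmWRKY33	IIe	Chr7	10670375	10672822	-	1017	338	37204.4243	5.2683	72.40296	-0.86982
Vmy07g25848	VmWRKY34	IId	Chr7	28979073	28980568	+	1038	345	37872.4647	9.7013	44.33942	-0.63072
Vmy08g19321	VmWRKY35	I	Chr8	8189304	8193703	-	1566	521	57275.1267	7.6594	53.98618	-0.78061
Vmy08g19634	VmWRKY36	IId	Chr8	12539067	12540851	+	975	324	35083.2628	9.5829	49.67099	-0.5071
Vmy08g20363	VmWRKY37	IIb	Chr8	26539533	26543458	-	1257	418	46326.055	6.7756	39.74285	-0.76555
Vmy08g20364	VmWRKY38	IIb	Chr8	26567087	26572765	-	1314	437	48350.2147	8.0178	44.91215	-0.78558
Vmy08g20862	VmWRKY39	III	Chr8	33668487	33685457	+	2013	670	75108.3868	6.8035	52.55225	-0.57209
Vmy08g20951	VmWRKY40	III	Chr8	35084050	35087270	+	726	241	27218.4897	9.0240	45.36892	-0.64398
Vmy08g20953	VmWRKY41	III	Chr8	35124873	35128367	+	726	241	27276.5258	8.8811	45.29091	-0.66598
Vmy08g20957	VmWRKY42	III	Chr8	35152034	35152550	-	336	111	13001.3469	6.8845	33.74234	-0.95405
Vmy08g20958	VmWRKY43	III	Chr8	35155907	35158286	-	351	116	13315.6492	6.3954	48.45517	-0.75517
Vmy09g21848	VmWRKY44	IIa	Chr9	5768052	5770593	+	987	328	36404.0856	7.6022	48.30549	-0.76738
Vmy09g23773	VmWRKY45	I	Chr9	35699795	35704437	-	1659	552	61427.4531	7.1727	59.53261	-0.97409
Vmy09g23833	VmWRKY46	III	Chr9	36446627	36448661	-	1008	335	37488.9147	5.4796	57.01851	-0.78657
Vmy09g23834	VmWRKY47	III	Chr9	36456426	36458322	-	981	326	36383.8599	5.9442	56.7635	-0.7227
Vmy10g9485	VmWRKY48	IIa	Chr10	4985336	4988127	-	870	289	32320.8629	6.3253	39.20208	-0.76332
Vmy10g9486	VmWRKY49	IIa	Chr10	5039428	5040970	+	540	179	19928.3004	8.6561	41.61508	-0.54078
Vmy11g4858	VmWRKY50	III	Chr11	22694878	22709418	+	1887	628	68221.588	5.7820	60.61369	-0.63392
Vmy11g4864	VmWRKY51	III	Chr11	22834006	22838063	-	951	316	35353.069	6.0694	57.9981	-0.70475
Vmy11g5266	VmWRKY52	IIe	Chr11	27599930	27601824	+	1050	349	37869.319	5.2802	60.43413	-0.75387
Vmy11g5322	VmWRKY53	III	Chr11	28097858	28099773	-	1152	383	42063.9735	5.9608	54.54885	-0.72298
Vmy12g1272	VmWRKY54	III	Chr12	11342519	11344263	+	1071	356	40375.9677	5.5414	46.38343	-0.88736
Vmy12g1322	VmWRKY55	IIc	Chr12	11966502	11968411	+	498	165	18670.9435	9.8000	32.01515	-0.85818
Vmy12g1324	VmWRKY56	IIe	Chr12	11987949	11989528	-	957	318	34707.0416	5.4257	54.09343	-0.53899
Vmy12g2389	VmWRKY57	I	Chr12	28589923	28593312	-	1644	547	60328.8928	8.4261	56.26289	-0.9947
Vmy12g2722	VmWRKY58	I	Chr12	32281670	32282541	+	693	230	25178.2666	6.4438	66.10478	-0.94739
Vmy12g2723	VmWRKY59	IId	Chr12	32286557	32288334	+	1023	340	38242.1155	9.7851	58.70412	-0.78235
Vmy12g371	VmWRKY60	III	Chr12	776559	778122	-	963	320	36043.8189	4.8940	38.90625	-0.60844
Vmy12g391	VmWRKY61	IIe	Chr12	961923	971203	-	2223	740	82707.5643	4.9592	53.45962	-0.44878
Vmy12g427	VmWRKY62	IIc	Chr12	1332136	1333788	-	597	198	22659.3469	9.1573	49.19899	-0.82424
Vmy12g435	VmWRKY63	IIe	Chr12	1390928	1392563	-	969	322	35739.1232	5.4169	61.10155	-0.85621
Vmy12g744	VmWRKY64	IIc	Chr12	4792418	4798547	-	708	235	26134.3628	7.1288	50.72255	-0.97064
VmyS4054g6302	VmWRKY65	IIb	S4054	11361	14074	+	1164	387	41562.6356	8.9565	47.0261	-0.54419
VmyS5938g36257	VmWRKY66	I	S5938	264671	269317	+	1128	375	41777.2506	6.9077	44.0112	-0.72293
VmyS6208g149	VmWRKY67	IIc	S6208	30683	48873	-	1812	603	66813.4835	9.3106	43.03997	-0.62919
VmyS7930g26553	VmWRKY68	IV	S7930	47310	57551	+	1482	493	56297.4289	9.0159	54.64016	-0.52312
VmyS8810g36160	VmWRKY69	IV	S8810	23416	30743	-	1170	389	43454.744	5.6507	54.54267	-0.70103
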