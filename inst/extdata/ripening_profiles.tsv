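gene_id	annotation	group	FS1	FS2	FS3	FS4	FS5
Unigene86203	Sucrose phosphate synthase	I_up	0.35	0.54	1.39	1.84	0.84
Unigene51453	Starch synthase	I_up	6.75	11.07	21.3	19.69	30.83
Unigene28216	Alkaline invertase	I_up	66.27	107.11	49.35	209.27	190.33
Unigene31510	Phosphofructokinase	I_up	1.21	0.89	15.25	21.55	25.8
Unigene79028	Maltose transporter	I_up	30.11	34.45	35.17	72.65	123.31
Unigene7706	Aldehyde dehydrogenase	I_up	48.28	59.44	87.67	93.03	102.54
Unigene11393	Expansin	I_up	21.63	20.35	39.33	74.99	148.11
Unigene84426	ACC oxidase	I_up	8.82	13.57	13.69	6.68	159
Unigene41650	4-Hydroxyphenylpyruvate dioxygenase	I_up	0	0.54	3.47	4.01	5.36
Unigene49425	Leucoanthocyanidin dioxygenase	I_up	1.73	11.07	13.34	49.77	36.19
Unigene78545	Auxin influx transport protein	II_down	130.12	120.31	136.76	5.97	32.84
Unigene28595	Sucrose synthase	II_down	1120.57	775.21	201.84	18.2	5.7
Unigene2239	Pyrophosphate-dependent phosphofructo-1-kinase	II_down	28.38	16.42	2.08	3.01	1.01
Unigene82187	Alcohol acyl-transferase	II_down	179.78	215.27	80.22	12.86	19.43
Unigene21328	Alcohol acyl-transferase	II_down	185.49	154.04	102.91	14.53	9.55
Unigene41185	Alcohol acyl-transferase	II_down	958.95	738.98	286.74	201.42	84.78
Unigene24664	Flavonoid 3-hydroxylase	II_down	114.55	62.47	0	3.67	0.34
Unigene89425	COL domain class transcription factor	II_down	100.88	80.86	13.34	10.52	4.36
Unigene40707	Arogenate/prephenate dehydratase	II_down	309.04	207.23	45.74	17.04	9.21
Unigene42300	UDPG flavonoid 7-O-glucosyltransferase	II_down	125.62	192.42	72.25	34.07	67.52
Unigene28017	NAD-dependent sorbitol dehydrogenase	III_low_high_low	9.52	6.96	21.66	11.69	4.02
Unigene48458	NAD-dependent sorbitol dehydrogenase	III_low_high_low	65.58	60.15	208.43	94.87	28.15
Unigene40996	p-Hydroxyphenylpyruvate dioxygenase	III_low_high_low	0.52	1.25	12.13	6.68	8.88
Unigene36705	Cytochrome P450	III_low_high_low	36.68	39.98	208.77	167.35	69.7
Unigene1335	Cytochrome P450	III_low_high_low	12.46	8.21	77.96	21.38	11.9
Unigene15706	Salt-tolerance protein	III_low_high_low	14.36	16.78	83.86	18.2	13.57
Unigene6651	DELLA protein	III_low_high_low	44.99	40.7	80.74	32.45	1.44
Unigene29424	Polyphenol oxidase	III_low_high_low	33.57	28.02	79.52	40.92	14.07
Unigene2416	Gibberellin oxidase	III_low_high_low	0.35	1.61	77.96	17.7	0
Unigene1535	S6 ribosomal protein	IV_constitutive	650.26	506.57	717.1	432.91	403.28
Unigene42402	Structural molecule activity	IV_constitutive	505.09	381.09	387.23	437.58	380.99
Unigene41042	DEAD-box RNA helicase-like protein	IV_constitutive	481.38	399.83	458.09	641.68	533.46
Unigene41056	Large ribosomal subunit	IV_constitutive	333.09	256.14	291.59	243.18	225.51
Unigene40598	Plasma membrane ATPase	IV_constitutive	29.93	22.13	20.62	50.1	3.57
Unigene41711	Plasma membrane intrinsic protein	IV_constitutive	19.38	28.92	41.23	23.88	21.11
Unigene8634	Plasma intrinsic protein	IV_constitutive	1121.95	866.6	964.51	974.21	799.18
Unigene13819	BHLH domain class transcription factor	IV_constitutive	212.49	243.11	169.79	168.85	206.92
Unigene3327	60S ribosomal protein L35a	IV_constitutive	180.65	182.6	166.5	154.99	138.73
Unigene40848	Ribosomal protein S21e	IV_constitutive	173.03	218.12	188.33	170.36	182.62
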