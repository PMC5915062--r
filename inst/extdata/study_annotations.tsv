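sample_id	group	age	figo_stage
1218	early_cancer	50	Ib2
1230	early_cancer	44	IIb
1239	early_cancer	43	Ib1
1291	early_cancer	34	Ib2
1298	early_cancer	80	Ib2
2110	early_cancer	77	IIb
2146	early_cancer	46	Ib2
2163	early_cancer	39	Ib1
2180	early_cancer	74	IIb
2246	early_cancer	73	Ib1
2252	early_cancer	44	Ib2
1225	late_cancer	58	IIIb
1348	late_cancer	71	IIIa
1685	late_cancer	26	IIIb
1966	late_cancer	75	IVb
1981	late_cancer	68	IIIb
1998	late_cancer	72	IIIb
2008	late_cancer	84	IIIa
2087	late_cancer	49	IIIb
2247	late_cancer	76	IIIb
2265	late_cancer	83	IVb
2297	late_cancer	52	IVa
1247	healthy_epithelium	43	NA
1262	healthy_epithelium	51	NA
1315	healthy_epithelium	36	NA
1477	healthy_epithelium	41	NA
1516	healthy_epithelium	39	NA
1525	healthy_epithelium	41	NA
1542	healthy_epithelium	46	NA
1826	healthy_epithelium	45	NA
1849	healthy_epithelium	51	NA
1936	healthy_epithelium	41	NA
1948	healthy_epithelium	60	NA
2000	healthy_epithelium	41	NA
2001	healthy_epithelium	49	NA
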