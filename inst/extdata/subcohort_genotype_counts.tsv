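gene	snp_id	sex	n_total	af_pct	pct_het	n_het	pct_hom	n_hom
GP6	rs1613662	female	6909	82.7	29.0	2005	68.2	4708
GP6	rs1613662	male	6160	82.5	28.3	1744	68.4	4209
F12	rs1801020	female	6909	74.6	37.2	2517	56.0	3788
F12	rs1801020	male	6160	74.2	38.9	2348	54.7	3304
F5	rs4524	female	6909	72.8	39.2	2706	53.2	3677
F5	rs4524	male	6160	72.9	39.3	2416	53.2	3277
F11	rs2036914	female	6909	53.3	50.4	3479	28.1	1940
F11	rs2036914	male	6160	52.8	49.9	3054	27.9	1706
STXBP5	rs1039084	female	6909	51.3	50.4	3482	26.1	1800
STXBP5	rs1039084	male	6160	51.7	50.4	3100	26.5	1631
TC2N	rs1884841	female	6909	43.2	48.1	3319	19.2	1323
TC2N	rs1884841	male	6160	42.9	48.4	2980	18.6	1148
KNG1	rs710446	female	6909	41.5	48.9	3379	17.0	1176
KNG1	rs710446	male	6160	41.0	47.9	2947	17.0	1048
F11	rs2289252	female	6909	39.3	47.5	3275	15.6	1077
F11	rs2289252	male	6160	39.0	47.3	2913	15.3	944
ABO	rs8176719	female	6909	38.3	45.9	3166	15.3	1056
ABO	rs8176719	male	6160	38.4	46.7	2861	15.1	922
VWF	rs1063857	female	6909	38.3	46.4	2878	15.0	932
VWF	rs1063857	male	6160	38.0	46.8	2611	14.6	812
F13	rs5985	female	6909	27.2	40.0	2692	7.2	484
F13	rs5985	male	6160	26.1	38.2	2291	7.1	423
FGG	rs2066865	female	6909	23.6	36.1	2845	5.6	386
FGG	rs2066865	male	6160	24.3	36.6	2255	6.0	370
SERP	rs2227589	female	6909	8.8	15.8	1091	0.9	59
SERP	rs2227589	male	6160	8.7	15.9	978	0.8	48
C4BPB	rs3813948	female	6909	7.7	14.3	986	0.6	39
C4BPB	rs3813948	male	6160	7.6	14.0	862	0.6	39
FVL	rs6025	female	6909	3.3	6.3	434	0.1	10
FVL	rs6025	male	6160	3.5	6.8	420	0.1	5
F2	rs3136520	female	6909	3.1	6.0	413	0.1	7
F2	rs3136520	male	6160	3.0	5.7	350	0.2	9
F2	rs1799963	female	6909	0.6	1.2	85	0.0	0
F2	rs1799963	male	6160	0.7	1.4	88	0.0	0
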