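gene	snp_id	sex	prevalence	hr	hr_low	hr_high	paf_pct	paf_low	paf_high
ABO	rs8176719	female	0.61	1.33	1.15	1.55	16.9	5.8	28.0
ABO	rs8176719	male	0.62	1.44	1.23	1.69	21.3	9.6	32.5
C4BPB	rs3813948	female	0.15	1.01	0.83	1.23	0.2	-3.5	4.2
C4BPB	rs3813948	male	0.15	0.93	0.75	1.16	-1.0	-4.8	2.9
FGG	rs2066865	female	0.42	1.15	1.00	1.33	6.0	-1.8	14.2
FGG	rs2066865	male	0.43	1.20	1.03	1.39	7.8	-0.5	16.0
FVL	rs6025	female	0.06	2.48	2.04	3.00	8.7	5.4	12.3
FVL	rs6025	male	0.07	2.17	1.76	2.69	7.5	4.0	11.2
F2	rs1799963	female	0.01	1.17	0.65	2.13	0.2	-0.8	1.5
F2	rs1799963	male	0.01	1.79	1.13	2.81	1.1	-0.3	2.9
F2	rs3136520	female	0.06	0.95	0.70	1.28	-0.3	-2.5	2.1
F2	rs3136520	male	0.06	1.16	0.85	1.57	0.9	-1.6	3.7
F5	rs4524	female	0.92	1.27	0.95	1.70	20.0	-10.9	47.3
F5	rs4524	male	0.92	1.97	1.33	2.92	47.3	19.0	72.1
F11	rs2036914	female	0.79	1.27	1.05	1.54	17.6	0.4	34.1
F11	rs2036914	male	0.78	1.18	0.98	1.42	12.2	-5.5	29.2
F11	rs2289252	female	0.63	1.28	1.10	1.49	15.1	3.4	26.7
F11	rs2289252	male	0.63	1.19	1.01	1.39	10.4	-2.0	22.4
F12	rs1801020	female	0.93	1.04	0.75	1.44	3.6	-38.3	38.3
F12	rs1801020	male	0.94	0.89	0.64	1.23	-11.1	-57.8	29.9
F13	rs5985	female	0.47	1.07	0.92	1.25	3.3	-6.2	2.1
F13	rs5985	male	0.45	1.15	0.97	1.35	6.1	-3.6	15.6
GP6	rs1613662	female	0.97	0.90	0.60	1.37	-10.3	-74.2	44.6
GP6	rs1613662	male	0.97	1.62	0.94	2.80	37.5	-10.2	76.4
KNG1	rs710446	female	0.66	1.07	0.92	1.24	4.2	-8.1	16.7
KNG1	rs710446	male	0.65	0.97	0.83	1.14	-1.7	-15.1	11.2
SERP	rs2227589	female	0.17	1.20	1.01	1.43	3.2	-0.9	7.7
SERP	rs2227589	male	0.17	1.00	0.80	1.20	-0.2	-4.4	4.1
STXBP5	rs1039084	female	0.76	1.15	0.97	1.37	0.1	-5.3	27.0
STXBP5	rs1039084	male	0.77	1.03	0.86	1.22	1.9	-15.9	18.8
TC2N	rs1884841	female	0.67	1.20	1.02	1.40	11.6	-1.3	24.4
TC2N	rs1884841	male	0.67	1.03	0.88	1.20	2.1	-11.8	15.9
VWF	rs1063857	female	0.61	1.05	0.91	1.22	2.7	-7.5	13.6
VWF	rs1063857	male	0.61	1.01	0.87	1.18	0.7	-10.6	12.0
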