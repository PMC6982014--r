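metric	unit	treatment	mean	sd	n	letter
Chl_a	mg/g FW	CK	1.653	0.021	3	A
Chl_a	mg/g FW	Cd	1.146	0.014	3	C
Chl_a	mg/g FW	CdN	1.521	0.039	3	B
Chl_b	mg/g FW	CK	0.571	0.013	3	A
Chl_b	mg/g FW	Cd	0.267	0.007	3	B
Chl_b	mg/g FW	CdN	0.629	0.026	3	A
Total_Chl	mg/g FW	CK	2.224	0.017	3	A
Total_Chl	mg/g FW	Cd	1.413	0.011	3	B
Total_Chl	mg/g FW	CdN	2.150	0.033	3	A
Pnmax	umolCO2.m-2.s-1	CK	14.73	0.25	3	A
Pnmax	umolCO2.m-2.s-1	Cd	7.17	0.34	3	C
Pnmax	umolCO2.m-2.s-1	CdN	11.16	0.51	3	B
R	umolCO2.m-2.s-1	CK	5.21	0.19	3	A
R	umolCO2.m-2.s-1	Cd	3.39	0.23	3	B
R	umolCO2.m-2.s-1	CdN	5.15	0.32	3	A
AQE	molCO2.m-1.photon	CK	0.62	0.002	3	A
AQE	molCO2.m-1.photon	Cd	0.27	0.004	3	C
AQE	molCO2.m-1.photon	CdN	0.45	0.002	3	B
gs	mmol.m-2.s-1	CK	0.58	0.001	3	A
gs	mmol.m-2.s-1	Cd	0.31	0.002	3	B
gs	mmol.m-2.s-1	CdN	0.49	0.003	3	A
FvFm	ratio	CK	0.823	0.012	3	A
FvFm	ratio	Cd	0.531	0.007	3	C
FvFm	ratio	CdN	0.709	0.004	3	B
Cd_soil	mg/kg	CK	0.68	0.002	3	C
Cd_soil	mg/kg	Cd	221.19	3.42	3	A
Cd_soil	mg/kg	CdN	152.13	2.45	3	B
Cd_root	mg/kg	CK	2.77	0.05	3	C
Cd_root	mg/kg	Cd	128.56	5.21	3	B
Cd_root	mg/kg	CdN	167.50	5.65	3	A
Cd_leaf	mg/kg	CK	1.41	0.02	3	C
Cd_leaf	mg/kg	Cd	78.09	2.58	3	B
Cd_leaf	mg/kg	CdN	124.52	3.52	3	A
H2O2	nmol/g FW	CK	52.9	3.4	3	C
H2O2	nmol/g FW	Cd	452.7	5.9	3	A
H2O2	nmol/g FW	CdN	132.1	3.6	3	B
MDA	umol/g FW	CK	9.24	1.2	3	C
MDA	umol/g FW	Cd	22.99	1.4	3	A
MDA	umol/g FW	CdN	13.21	1.5	3	B
GSH	nmol/g FW	CK	24.6	1.27	3	C
GSH	nmol/g FW	Cd	52.7	2.41	3	B
GSH	nmol/g FW	CdN	106.4	3.45	3	A
PCs	nmol/g FW	CK	121.3	5.45	3	C
PCs	nmol/g FW	Cd	325.9	6.42	3	B
PCs	nmol/g FW	CdN	543.4	4.76	3	A
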