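protein_id	gene_name	family	substrate	location	1.5hS/FL	1.5hNaS/NaFL	7dS/FL	7dNaS/NaFL	14dS/FL	14dNaS/NaFL
81048	SiPMA1	P-ATPase	H+	PM	1.24	0	0	0	0	0
71428		F-ATPase	H+	Vacuole	0	0	1.22	1.33	1.31	1.69
74605		F-ATPase	H+	Vacuole	0	1.70	0	0	0	0
79610	SiHAK1	KUP	K+	PM	1.85	1.88	2.48	1.04	1.99	2.55
75409	SiKHA1	CPA2	K+, H+	ER, Golgi	0	-1.30	0	0	0	0
75414	SiKHA2	CPA2	K+, H+	ER, Golgi	0	-1.69	1.09	1.50	1.06	1.36
72635	SiENA1	P-ATPase	K+, Na+	PM	0	3.120	7.80	9.77	10.50	11.41
72634	SiENA5	P-ATPase	K+, Na+	PM	0	-1.37	1.27	0	1.52	0
77504	SiTRK2	Trk	K+, Na+	PM	0	0	0	1.09	0	0
72636	SiVNX1	CPA2	Na+, H+	Mitochondria	0	1.06	1.08	0	0	0
74006	SiNHX1	CPA1	Na+, H+	Vacuole	0	0	0	-1.40	-1.26	-1.08
75037	YVC1	TRP-CC	Ca2+	Vacuole	0	1.01	0	0	0	0
71526	Annexin D1	alpha-Type Channels	Ca2+		2.03	2.27	0	-1.80	0	0
74614	VCX1	CaCA	Ca2+, H+	Vacuole	0	-2.45	0	0	0	-1.75
72312	CAX	CaCA	Ca2+, H+	Vacuole	0	7.86	-5.89	-5.02	-6.10	-5.72
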