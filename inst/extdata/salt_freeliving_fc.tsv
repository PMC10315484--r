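protein_id	piin_id	gene_name	family	substrate	location	NaFL1.5h/FL1.5h	NaFL7d/FL7d	NaFL14d/FL14d
72634	PIIN_01840	SiENA5	P-ATPase	K+, Na+	PM	1.94	1.39	1.64
75414	PIIN_04607	SiKHA1	CPA2	K+, H+	ER, Golgi	1.04	0	0
76836	PIIN_06030		MFS	Metabolites	PM	1.49	0	0
80618	PIIN_09801		MFS	Metabolites	PM	1.41	0	0
79280	PIIN_08471		MFS	Metabolites	PM	1.27	0	1.34
76839	PIIN_06033		MFS	Metabolites	PM	0	0	1.47
73068	PIIN_02271		OPT	Oligopeptides	ER	0	0	1.14
77505	PIIN_06701		MFS	Vitamins	PM	0	0	1.15
72591	PIIN_01799		MFS	Glucose	PM	1.59	0	0
75164	PIIN_04361		MFS	Xylose	PM	0	1.05	0
75943	PIIN_05137		MFS	Galactose, H+	PM	0	1.41	0
71636	PIIN_00866		PiT	Phosphate, Na+	PM	0	1.5	0
72809	PIIN_02015		Triflin or CRISP	None	?	0	1.51	0
79846	PIIN_09033		DMT	Unknown	?	0	1.07	0
72312	PIIN_01532		CaCA	Ca2+, H+	Vacuole	-2.96	0	0
78458	PIIN_07651		Calmodulin	Phospholipids	?	-1.88	0	0
74378	PIIN_03575		NPC	Phospholipids	Nucleus	-1.14	0	0
73489	PIIN_02689		NDH	H+	Mitochondria	-1.06	0	0
72519	PIIN_01732		QCR	H+	Mitochondria	-1.09	0	0
75212	PIIN_04408		NDH	H+	Mitochondria	0	0	-1.02
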