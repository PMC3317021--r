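clone	gene	quantity	control	scomp	dop
H17813	TOP2A	5.86	++	+++	N
H59203	CDC6	2.87	+++	++++	N
H23044	TEM7	2.45	++	+++	+
H64260	PRKAG2	2.23	N	N	N
H18802	Link-GEFII	2.19	++++	++++	+
H46384	PRO2521	2.18	++++	++	N
T85025		1.97	++++	++++	N
H29706	GPC5	1.79	+++	++++	N
H59714	AK2	1.58	++	+++	N
321749		1.55	+	+++	N
H20867	PCDH9	1.46	+++	++++	N
H93272	CPM	1.42	+	+	N
AA011584		1.38	+	++	+
W24419		1.36	+++	+	N
H85791		1.32		+++	+
H01255	CLN5	1.22	+++	++	+
H62028	DYRK3	1.18	+	+	+
H14685	PTK2	1.06	N	N	N
R06520	PRKCBP1	0.98	N	N	N
R24935	CDA08	0.76	-	N	N
H46055	KIAA0725	0.75	+	N	N
H53288	BAG4	0.71	N	N	N
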