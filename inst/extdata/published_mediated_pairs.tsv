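cpg_id	meth_diff	p_m_y	gene	cpg_chr	cpg_pos	snp_id	snp_chr	snp_pos	p_g_m	p_g_y	p_cit
cg03718677	-0.08	4.60E-03	TMOD4	1	149414890	rs1250220	2	216320050	2.30E-07	0.023	0.023
cg03718677	-0.08	4.60E-03	TMOD4	1	149414890	rs1250252	2	216313591	1.70E-07	0.029	0.029
cg09822001	0.11	5.50E-04	APOA1BP	1	154827958	rs2919303	8	62214493	1.50E-07	0.027	0.027
cg10636246	-0.11	2.70E-04	AIM2	1	157313597	rs11120596	1	215850817	7.60E-07	0.002	0.002
cg10636246	-0.11	2.70E-04	AIM2	1	157313597	rs460380	21	46028864	5.30E-07	0.01	0.01
cg13721560	0.07	7.90E-03	LRPPRC	2	44076072	rs2289840	3	124181739	9.40E-08	0.041	0.041
cg10061138	-0.09	8.30E-04	STAB1	3	52504125	rs11884397	2	23885388	3.10E-07	0.002	0.002
cg25086702	0.1	1.70E-03	HMGB2	4	174492134	rs11210834	1	43787437	7.10E-08	0.048	0.048
cg24136586	0.1	5.50E-03	ATG10	5	81304122	rs3800524	6	168302015	1.80E-06	0.034	0.034
cg01495509	0.08	5.30E-03	KCNMB1	5	169748956	rs4457945	15	54608127	2.20E-08	0.019	0.019
cg25553916	0.06	6.90E-04	FLJ22318	5	177491361	rs2254066	2	29889019	2.60E-07	0.003	0.003
cg25553916	0.06	6.90E-04	FLJ22318	5	177491361	rs2631958	2	29958841	7.10E-07	0.009	0.009
cg25553916	0.06	6.90E-04	FLJ22318	5	177491361	rs6754181	2	29966380	3.10E-07	0.003	0.003
cg19436567	0.12	1.50E-04	ARID1B	6	157141067	rs12362925	11	16875419	7.80E-08	0.029	0.029
cg08142684	0.13	2.70E-04	TCP1	6	160129858	rs9792311	8	123940585	7.40E-07	0.023	0.023
cg05109049	0.09	5.30E-03	EVI2B	17	26665459	rs2294405	6	99292136	1.60E-06	0.013	0.013
cg00021527	0.09	5.20E-03	TAF15	17	31160293	rs10488500	7	76841259	2.50E-07	0.046	0.046
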