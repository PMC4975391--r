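patient_id	sample_id	gene	variant_type	cdna_change	protein_change	printed_af	mutant_reads	ref_reads	origin	validation	functional_class
P1	S1	TENM2	missense	c.6241G>A	p.D2081N	0.232	36	119	somatic	WGS	low
P1	S1	B3GALT5	missense	c.673G>A	p.V225M	0.146	19	111	somatic	WGS	medium
P1	S1	MAZ	missense	c.1148C>T	p.A383V	0.462	6	7	somatic	WGS	neutral
P1	S1	GZF1	missense	c.1021G>A	p.G341S	0.215	23	84	somatic	RNA-seq	low
P1	S2	TENM2	missense	c.6241G>A	p.D2081N	0.341	15	29	somatic	seen in S1	low
P1	S2	B3GALT5	missense	c.673G>A	p.V225M	0.293	60	145	somatic	seen in S1	medium
P1	S2	MAZ	missense	c.1148C>T	p.A383V	NA	NA	NA	somatic	not seen	neutral
P1	S2	GZF1	missense	c.1021G>A	p.G341S	0.261	30	85	somatic	RNA-seq	low
P3	S4	ATP7B	missense	c.2173A>T	p.R725W	0.404	40	59	somatic	Sanger	medium
P3	S4	GPT2	nonsense	c.274C>T	p.R92*	0.400	46	69	somatic	Sanger	NA
P4	S5	DBC1	missense	c.446G>A	p.R149H	0.275	11	29	somatic	RNA-seq	neutral
P4	S5	LSS	missense	c.1010C>T	p.P337L	0.333	31	62	somatic	RNA-seq	high
P4	S5	DSTYK	missense	c.865A>G	p.I289V	0.353	12	22	somatic	RNA-seq	medium
P4	S5	MCLN2	missense	c.596C>G	p.S199C	0.120	3	22	somatic	RNA-seq	medium
P4	S5	DYNC1H1	missense	c.8635A>G	p.K2879E	0.053	4	71	somatic	RNA-seq	medium
P5	S6	CNOT3	missense	c.38G>A	p.R13H	0.182	32	144	somatic	RNA-seq	medium
P5	S6	KIAA1370	missense	c.832G>A	p.E278K	0.276	16	42	somatic	RNA-seq	low
P5	S6	ABCB4	missense	c.2339G>A	p.G780D	0.278	40	104	somatic	RNA-seq	high
P5	S6	VILL	missense	c.1879G>A	p.A627T	0.288	15	37	somatic	RNA-seq	neutral
P5	S6	EFEMP1	missense	c.1279C>T	p.R427W	0.304	21	48	somatic	RNA-seq	medium
P5	S6	TNK2	missense	c.804C>G	p.I268M	0.056	4	68	somatic	RNA-seq	medium
P6	S7	SPEN	missense	c.5437G>A	p.A1813T	0.138	12	75	somatic	Sanger	neutral
P6	S7	SNRPA	missense	c.718G>C	p.V240L	0.100	9	81	somatic	RNA-seq	medium
P6	S7	SGOL2	missense	c.1433G>C	p.G478A	0.162	30	155	somatic	RNA-seq	low
P6	S7	CNIH3	missense	c.400G>A	p.E134K	0.364	40	70	somatic	RNA-seq	medium
P6	S7	GSK3B	splice	c.1195_splice	p.D399_splice	0.293	12	29	somatic	RNA-seq	NA
P6	S7	ATP1A1	missense	c.1696C>T	p.P566S	0.080	16	183	somatic	RNA-seq	low
P6	S7	THBS3	missense	c.1576G>C	p.D526H	0.087	9	94	somatic	RNA-seq	medium
P6	S7	ZNF304	nonsense	c.688A>T	p.K230*	0.075	6	74	somatic	RNA-seq	NA
P6	S7	SEL1L2	missense	c.511G>A	p.E171K	0.128	6	41	somatic	RNA-seq	medium
P6	S7	ZNF592	missense	c.3158C>G	p.P1053R	0.082	10	112	somatic	RNA-seq	neutral
P6	S7	THBS3	missense	c.1576G>C	p.D526H	0.087	9	94	somatic	RNA-seq	medium
P6	S7	TRPM6	missense	c.3965C>T	p.T1322I	0.164	31	158	somatic	RNA-seq	low
P13	S14	GIGYF1	missense	c.953G>T	p.G318V	0.227	17	58	somatic	Sanger	neutral
P13	S14	NEUROD4	missense	c.704C>T	p.S235L	0.183	28	125	somatic	Sanger	low
P13	S14	POLR3F	missense	c.321A>G	p.I107M	0.149	7	40	somatic	Sanger	medium
P13	S15	TMPPE	frameshift_del	c.139_143delCAGCT	p.QL47fs	0.119	77	570	somatic	Sanger	NA
P13	S15	KIAA0232	missense	c.1672A>G	p.M558V	0.195	160	660	somatic	Sanger	low
P13	S15	ANK2	missense	c.7060C>T	p.R2354C	0.233	179	590	somatic	Sanger	neutral
P13	S15	PHF1	missense	c.160G>T	p.V54L	0.221	147	518	somatic	Sanger	low
P13	S15	UBE3D	missense	c.344G>T	p.G115V	0.171	118	571	somatic	Sanger	medium
P13	S15	OR8G5	missense	c.931G>T	p.V311L	0.155	162	886	somatic	Sanger	low
P13	S15	ANKRD35	missense	c.200C>A	p.T67K	0.088	58	603	somatic	SNaPshot	neutral
P13	S15	ZNF804B	missense	c.643C>T	p.H215Y	0.057	48	799	somatic	SNaPshot	medium
P13	S17	WWTR1	missense	c.317C>T	p.P106L	0.841	37	7	somatic	Sanger	medium
P13	S17	NDUFA8	missense	c.284A>G	p.Q95R	0.847	294	53	somatic	Sanger	low
P13	S17	GCAT	missense	c.1201G>T	p.G401W	0.885	69	9	somatic	Sanger	high
P13	S17	ARHGAP35	missense	c.3818A>C	p.E1273A	0.782	68	19	somatic	Sanger	high
P13	S17	CCDC132	missense	c.2460A>C	p.L820F	0.882	45	6	somatic	Sanger	medium
P13	S18	MLKL	missense	c.553A>G	p.M185V	0.208	10	38	somatic	Sanger	low
P13	S18	USH2A	missense	c.9638C>A	p.P3213Q	0.221	73	258	somatic	Sanger	medium
P13	S18	CCDC39	missense	c.892C>T	p.R298C	0.326	29	60	somatic	Sanger	NA
P13	S18	LIPA	missense	c.739G>A	p.V247I	0.133	33	216	somatic	Sanger	neutral
P13	S18	ZNF821	missense	c.518C>G	p.S173W	0.258	54	155	somatic	Sanger	low
P13	S18	MIER2	missense	c.1514C>T	p.S505L	0.187	46	200	somatic	Sanger	low
P13	S18	GPR50	missense	c.1214A>G	p.K405R	0.092	22	218	somatic	SNaPshot	low
P13	S18	TUBB2A	inframe_del	c.89_103delTCGACCCCACAGGCA	p.IDPTG30del	0.090	7	71	somatic	Sanger	NA
P13	S20	ADAMTSL1	inframe_del	c.1387_1398delTGCATCGACCAT	p.CIDH463del	0.099	19	172	somatic	Sanger	NA
P13	S20	ZSCAN21	inframe_del	c.1225_1239delCTCCACACCGGAGAG	p.LHTGE409del	0.097	10	93	somatic	Sanger	NA
P13	S20	MAATS1	missense	c.743G>A	p.R248H	0.295	33	79	somatic	Sanger	medium
P13	S20	NCF1	missense	c.568G>A	p.E190K	0.274	51	135	somatic	Sanger	medium
P13	S21	UBE3D	frameshift_del	c.1130_1131delGC	p.R378fs	0.087	12	126	somatic	SNaPshot	NA
P13	S23	KIAA1107	missense	c.334G>A	p.V112I	0.222	8	28	somatic	Sanger	neutral
P13	S23	HOXD12	missense	c.491A>G	p.D164G	0.125	25	175	somatic	Sanger	medium
P13	S23	BAP1	missense	c.1550C>T	p.T517M	0.126	23	160	somatic	Sanger	low
P13	S23	TLL1	missense	c.1120C>T	p.H374Y	0.169	44	216	somatic	Sanger	low
P13	S23	MAATS1	missense	c.743G>A	p.R248H	0.247	20	61	somatic	Sanger	medium
P13	S23	NCF1	missense	c.568G>A	p.E190K	0.236	60	194	somatic	Sanger	medium
P13	S23	ATP9A	missense	c.2813T>G	p.I938S	0.222	8	28	somatic	SNaPshot	medium
P13	S24	ASPM	missense	c.2296C>T	p.R766C	0.271	97	261	somatic	SNaPshot	medium
P13	S24	TRIP12	splice	c.5470-2A>G	p.L1824_splice	0.254	36	106	somatic	Sanger	NA
P13	S24	MIS18BP1	missense	c.816C>A	p.S272R	0.333	54	108	somatic	Sanger	low
P13	S24	ZNF578	frameshift_del	c.1414_1417delAGAC	p.RH472fs	0.241	27	85	somatic	Sanger	NA
P13	S24	MAATS1	missense	c.743G>A	p.R248H	0.380	30	49	somatic	Sanger	medium
P13	S24	NCF1	missense	c.568G>A	p.E190K	0.267	60	165	somatic	Sanger	medium
P13	S24	ASPM	missense	c.247C>G	p.P83A	0.081	33	374	somatic	Sanger	medium
P13	S26	WWC1	missense	c.2896C>T	p.R966C	0.352	51	94	somatic	Sanger	medium
P13	S27	TRIP12	missense	c.4784G>A	p.R1595Q	0.216	19	69	somatic	Sanger	high
P13	S27	WDR55	missense	c.790G>A	p.E264K	0.466	54	62	somatic	Sanger	medium
P13	S27	LILRB5	missense	c.1291G>A	p.D431N	0.106	7	59	somatic	Sanger	low
P13	S27	EXOC3	missense	c.1975A>G	p.I659V	0.074	12	150	somatic	SNaPshot	low
P13	S29	PTPRF	missense	c.2269C>G	p.R757G	0.030	6	193	somatic	Sanger	medium
P13	S29	PDE2A	missense	c.930C>A	p.D310E	0.122	22	159	somatic	SNaPshot	medium
P13	S29	RNF24	missense	c.266A>G	p.D89G	0.329	69	141	somatic	Sanger	low
P13	S29	GRM3	missense	c.2498A>G	p.N833S	0.079	15	174	somatic	SNaPshot	medium
P13	S29	POLR2A	missense	c.2423C>G	p.P808R	0.070	15	198	somatic	SNaPshot	high
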