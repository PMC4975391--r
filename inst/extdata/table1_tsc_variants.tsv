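patient_id	sample_id	source	gene	variant_type	cdna_change	protein_change	printed_af	mutant_reads	ref_reads	origin	loh_annotation	loh_region_id	notes
P1	S1	abdominal LAM	TSC2	frameshift_del	c.2319delA	p.L773fs	0.54	49	41	somatic	Yes	NA	WGS,RNA-Seq
P1	S2	chylous fluid cell cluster	TSC2	frameshift_del	c.2319delA	p.L773fs	0.39	5	8	somatic	Yes	NA	NA
P2	S3	angiomyolipoma	TSC2	splice	c.976-15G>A	p.A326_splice	0.81	67	16	somatic	Yes	NA	WGS,RNA-Seq,LAM
P3	S4	angiomyolipoma cell line	TSC2	frameshift_del	c.2250delC	p.L750fs	0.60	55	36	somatic	Yes	NA	LAM
P4	S5	angiomyolipoma	TSC2	splice	c.4493+1G>A	p.S1498_splice	0.41	28	41	germline	2-hit	NA	RNA-Seq,TSC
P4	S5	angiomyolipoma	TSC2	frameshift_del	c.4765delC	p.P1589fs	0.44	28	36	somatic	2-hit	NA	TSC
P5	S6	angiomyolipoma	TSC2	nonsense	c.1195G>T	p.E399*	0.34	25	48	somatic	2-hit	NA	RNA-Seq
P5	S6	angiomyolipoma	TSC2	frameshift_del	c.2246delG	p.R749fs	0.26	21	61	somatic	2-hit	NA	NA
P6	S7	angiomyolipoma	TSC2	genomic_del	NA	NA	0.63	NA	NA	somatic	NA	NA	RNA-Seq,hom_del_50kb,single_loss_150kb
P7	S8	angiomyolipoma	TSC2	splice	c.2742+1G>A	p.K914_splice	0.28	15	38	somatic	2-hit	NA	no normal
P7	S8	angiomyolipoma	TSC2	inframe_del	c.5227_5244delCGGCTCCGCCACATCAAG	p.RLRHIK1743del	0.08	18	215	somatic	2-hit	NA	no normal
P8	S9	angiomyolipoma	TSC2	nonsense	c.3581G>A	p.W1194*	0.36	56	100	somatic	2-hit	NA	no normal
P8	S9	angiomyolipoma	TSC2	frameshift_del	c.4565_4566delAT	p.N1522fs	0.25	42	123	somatic	2-hit	NA	no normal
P9	S10	angiomyolipoma	TSC2	splice	c.3132-1G>C	p.R1044_splice	0.32	35	73	somatic	2-hit	NA	no normal
P9	S10	angiomyolipoma	TSC2	nonsense	c.4905C>A	p.C1635*	0.33	15	31	somatic	2-hit	NA	no normal
P10	S11	angiomyolipoma	TSC2	nonsense	c.3310C>T	p.Q1104*	0.35	8	15	somatic	2-hit	NA	no normal
P10	S11	angiomyolipoma	TSC2	splice	c.976-15G>A	p.A326_splice	0.23	44	144	somatic	2-hit	NA	no normal
P11	S12	angiomyolipoma	TSC2	nonsense	c.274G>T	p.E92*	0.38	6	10	somatic	2-hit	NA	no normal
P11	S12	angiomyolipoma	TSC2	nonsense	c.3259G>T	p.E1087*	0.24	38	119	somatic	2-hit	NA	no normal
P12	S13	angiomyolipoma	TSC2	nonsense	c.4762C>T	p.Q1588*	0.67	45	22	somatic	Yes	NA	no normal
P13	S14	angiomyolipoma	TSC2	frameshift_del	c.5135delC	p.A1712fs	0.72	84	32	germline	Yes	R1	TSC
P13	S15	angiomyolipoma	TSC2	frameshift_del	c.5135delC	p.A1712fs	0.60	370	248	germline	Yes	R1	TSC
P13	S16	angiomyolipoma	TSC2	frameshift_del	c.5135delC	p.A1712fs	0.36	69	121	germline	No	NA	TSC
P13	S17	angiomyolipoma	TSC2	frameshift_del	c.5135delC	p.A1712fs	0.74	119	42	germline	Yes	R1	TSC
P13	S18	angiomyolipoma	TSC2	frameshift_del	c.5135delC	p.A1712fs	0.75	102	34	germline	Yes	R1	TSC
P13	S19	angiomyolipoma	TSC2	frameshift_del	c.5135delC	p.A1712fs	0.53	86	76	germline	Yes	R1	TSC
P13	S20	angiomyolipoma	TSC2	frameshift_del	c.5135delC	p.A1712fs	0.64	96	53	germline	Yes	R2	TSC
P13	S21	angiomyolipoma	TSC2	frameshift_del	c.5135delC	p.A1712fs	0.64	93	53	germline	Yes	R3	TSC
P13	S22	angiomyolipoma	TSC2	frameshift_del	c.5135delC	p.A1712fs	0.50	95	97	germline	Yes	uncertain	TSC,low_purity
P13	S23	angiomyolipoma	TSC2	frameshift_del	c.5135delC	p.A1712fs	0.52	92	84	germline	Yes	R2	TSC
P13	S24	angiomyolipoma	TSC2	frameshift_del	c.5135delC	p.A1712fs	0.70	114	48	germline	Yes	R2	TSC
P13	S25	angiomyolipoma	TSC2	frameshift_del	c.5135delC	p.A1712fs	0.71	129	54	germline	Yes	R4	TSC
P13	S26	angiomyolipoma	TSC2	frameshift_del	c.5135delC	p.A1712fs	0.43	77	104	germline	2-hit	NA	TSC
P13	S26	angiomyolipoma	TSC2	frameshift_ins	c.888_889insT	p.F297fs	0.31	155	345	somatic	2-hit	NA	TSC
P13	S27	angiomyolipoma	TSC2	frameshift_del	c.5135delC	p.A1712fs	0.35	73	134	germline	2-hit	NA	TSC
P13	S27	angiomyolipoma	TSC2	frameshift_ins	c.2035-2036insG	p.V679fs	0.12	26	185	somatic	2-hit	NA	TSC
P13	S28	angiomyolipoma	TSC2	frameshift_del	c.5135delC	p.A1712fs	0.34	72	137	germline	No	NA	TSC
P13	S29	angiomyolipoma	TSC2	frameshift_del	c.5135delC	p.A1712fs	0.74	145	51	germline	Yes	R5	TSC
P14	S30	angiomyolipoma	TSC1	nonsense	c.2074C>T	p.R692*	0.72	121	46	germline	9q LOH	NA	no normal,TSC
P14	S31	angiomyolipoma	TSC1	nonsense	c.2074C>T	p.R692*	0.58	83	60	germline	9q LOH	NA	no normal,TSC
P15	S32	angiomyolipoma	TSC2	splice	c.2742+1G>A	p.K914_splice	0.50	125	123	somatic	Yes	NA	no normal
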