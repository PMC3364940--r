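group	gene	chromosome	anova_stars	ratio_Ts65Dn	stars_Ts65Dn	ratio_Ms5Yah	stars_Ms5Yah	ratio_Ts65Dn_Ms5Yah	stars_Ts65Dn_Ms5Yah
G1	AU021092	16	2	1.26	1	0.87	0	1.32	2
G1	Heph	X	3	1.27	1	1.11	0	1.43	2
G1	Fbln2	6	2	1.30	2	0.96	0	1.34	3
G1	AI593442	9	2	1.83	2	0.94	0	1.68	2
G1	Pdgfd	9	1	1.23	2	0.94	0	1.21	1
G1	F5	1	0	1.49	2	1.08	0	1.22	0
G1	Vwf	6	0	1.32	2	1.02	0	1.27	2
G1	Pcbd1	10	0	1.66	2	0.86	0	1.34	0
G1	P2ry12	3	0	1.26	2	1.01	0	1.22	2
G1	Lrp2bp	8	0	0.65	3	0.83	0	0.64	3
G1	Htr2a	14	0	0.70	3	0.83	0	0.67	2
G1	Clk1	7	0	0.77	1	0.85	0	0.72	2
G2	Irf7	7	0	1.37	1	0.67	0	0.93	0
G2	Zfp583	7	0	1.29	2	0.72	0	0.99	0
G2	Slc38a4	15	2	0.76	3	1.27	0	0.86	0
G2	Slc8a1	17	0	0.80	0	1.34	0	1.03	0
G2	Adam19	11	1	1.28	0	1.89	1	1.06	0
G2	Vmn2r86	10	1	1.59	2	1.38	2	1.10	0
G3	Wrb	16	3	1.22	3	0.89	0	1.18	0
G3	St8sia5	18	0	1.27	2	1.19	0	1.18	0
G3	Slc39a6	18	0	1.25	2	0.97	0	1.14	0
G3	Abi3bp	16	0	1.42	2	1.03	0	1.20	0
G3	BC055004	5	0	1.50	2	0.84	0	1.14	0
G3	Dyrk1b	7	1	0.73	3	0.82	0	0.84	0
G3	Ypel2	11	1	0.79	0	1.18	0	0.90	0
G3	Chrna2	14	0	0.78	2	0.80	0	0.81	0
G3	Ldhd	8	0	0.79	2	0.93	0	0.86	0
G3	Gm16493	9	0	0.71	1	1.01	0	0.89	0
G3	Pm20d1	1	0	0.65	3	0.96	0	0.88	0
G3	Nudt8	19	1	0.79	2	1.05	0	0.94	0
G4	Carkd	8	1	0.93	0	0.79	2	0.91	0
G4	Amot	X	1	1.02	0	0.72	1	1.01	0
G4	Pnck	X	1	0.94	0	0.64	2	0.85	0
G4	Gm8566	6	1	1.13	0	0.74	2	0.96	0
G4	Gm5436	12	2	1.14	0	0.71	1	0.97	0
G4	Hmcn2	2	1	1.12	0	0.78	0	1.19	0
G4	Scn4b	9	2	1.06	0	0.34	1	1.12	0
G4	Rasl10b	11	1	0.90	0	0.72	0	1.02	0
G4	Tnxb	17	0	0.96	0	0.75	0	0.96	0
G4	Pde7b	10	0	0.87	0	0.73	1	0.90	0
G4	C1qa	4	0	1.01	0	0.74	0	1.07	0
G4	Ccne2	4	0	0.99	0	0.71	1	0.82	0
G4	Crnkl1	2	0	0.92	0	0.79	0	0.85	0
G4	Cerk	15	1	1.11	0	1.29	0	0.94	0
G4	2810410L24Rik	11	0	0.94	0	1.24	0	1.14	0
G4	Gm10400	6	0	0.86	0	1.28	0	0.91	0
G4	2210021J22Rik	15	0	1.05	0	1.35	0	1.08	0
G4	Fam189a1	7	0	1.01	0	1.23	0	1.15	0
G4	Adamts6	13	0	1.00	0	1.36	0	1.01	0
G4	Zc3h12c	9	0	1.09	0	1.30	0	1.08	0
G4	Lrrfip1	1	0	1.02	0	1.25	0	1.05	0
G4	Lce1m	3	0	1.07	0	1.25	0	1.15	0
G4	Fzd3	14	0	1.10	0	1.21	0	0.93	0
G4	Pnrc1	4	0	1.02	0	1.33	0	1.07	0
G4	Tnni1	1	1	1.01	0	1.34	2	1.13	0
G4	mIR697	4	1	0.99	0	1.25	2	1.06	0
G4	St3gal4	9	2	1.00	0	1.27	3	1.15	0
G4	Mapk4	18	1	0.86	0	1.28	1	0.91	0
G4	Ybx2	11	1	0.82	0	1.23	1	0.96	0
G4	Cass4	2	1	1.02	0	1.25	2	1.16	0
G4	Clec12b	6	1	0.93	0	1.33	1	1.05	0
G5	Ccl24	5	3	0.99	0	2.13	2	1.31	0
G5	ENSMUSG00000073686	4	1	1.00	0	1.22	3	1.23	2
G5	Olfr234	15	1	1.09	0	1.39	2	1.38	3
G5	Disp2	2	1	0.95	0	1.33	2	1.26	2
G5	Mmp9	2	0	0.99	0	1.78	0	1.53	0
G5	Tnrc4	3	0	1.04	0	1.29	0	1.28	1
G5	Loxhd1	18	0	1.14	0	1.32	0	1.20	2
G5	Adamts18	8	0	1.10	0	1.23	0	1.34	2
G5	mIR125a	17	0	1.13	0	1.27	0	1.22	2
G5	Grin2b	6	2	1.15	0	1.23	3	1.26	3
G6	Plvap	8	1	1.59	2	1.34	3	1.42	2
G6	S100a11	3	0	1.43	2	1.21	0	1.40	2
G6	Kctd15	7	0	1.21	2	1.30	0	1.30	2
G6	Abcd3	3	0	0.77	2	0.79	1	0.75	3
G6	Tubb1	2	0	1.93	2	1.17	0	1.50	0
G6	Ppbp	5	1	5.27	2	1.75	0	3.45	2
G7	Irs3	5	2	0.94	0	1.09	0	1.21	3
G7	Gon4l	3	0	0.84	0	0.91	0	0.79	3
G7	Sesn3	9	0	0.85	0	0.87	0	0.79	3
G7	Fam163a	1	0	1.07	0	1.00	0	1.21	2
G7	Slco3a1	7	0	1.03	0	1.14	0	1.20	2
G7	Aard	15	0	1.07	0	1.12	0	1.20	3
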