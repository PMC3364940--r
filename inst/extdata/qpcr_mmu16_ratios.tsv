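gene	ratio_Ts65Dn	sem_Ts65Dn	sig_Ts65Dn	ratio_Ts65Dn_Ms5Yah	sem_Ts65Dn_Ms5Yah	sig_Ts65Dn_Ms5Yah	ratio_Ms5Yah	sem_Ms5Yah	sig_Ms5Yah
Usp16	1.68	0.21	TRUE	1.16	0.30	FALSE	0.54	0.16	TRUE
Cct8	1.72	0.14	TRUE	1.01	0.14	FALSE	0.44	0.09	TRUE
Bach1	1.77	0.31	TRUE	1.10	0.22	FALSE	0.58	0.16	TRUE
Dyrk1a	1.57	0.12	TRUE	1.64	0.20	TRUE	1.06	0.10	FALSE
Sh3bgr	1.68	0.22	TRUE	1.57	0.27	TRUE	0.74	0.11	FALSE
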