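gene	classical	intermediate	non_classical	flag_classical	flag_intermediate	flag_non_classical
ACTB	0.86	0.68	0.97	0	0	0
ADAM17	0.00	0.00	0.00	1	1	1
BAX	0.00	0.00	0.00	1	1	1
BCL2	0.00	0.00	0.00	1	1	1
BCL2L1	0.94	0.00	0.00	0	1	1
C1QA	1.00	0.00	0.00	0	1	1
CCR1	0.00	0.00	0.31	1	1	0
CCR2	0.03	1.00	1.00	1	0	0
CCR5	1.00	0.99	1.00	0	0	0
CCR9	1.00	1.00	1.00	0	0	0
CD14	0.86	0.00	0.00	0	1	1
CD163	0.00	0.15	1.00	1	0	0
CD209	0.94	0.99	1.00	0	0	0
CD33	0.02	0.00	0.00	1	1	1
CD36	0.11	0.00	0.49	0	1	0
CD40	0.00	0.00	0.00	1	1	1
CD68	0.70	0.99	0.99	0	0	0
CD74	0.76	0.95	0.98	0	0	0
CD93	0.00	0.00	0.00	1	1	1
CLEC4E	0.00	1.00	1.00	1	0	0
CSF1R	0.00	0.94	0.00	1	0	1
CST3	0.52	0.62	0.88	0	0	0
CTSB	0.25	0.75	0.70	0	0	0
CTSK	0.00	0.00	0.00	1	1	1
CTSL	1.00	0.00	0.00	0	1	1
CTSS	0.85	0.99	0.99	0	0	0
CX3CR1	0.00	0.00	0.00	1	1	1
FCGR3A	0.05	0.96	0.95	1	0	0
HLA-DRA	0.90	0.94	0.61	0	0	0
HLA-DRB1	0.00	0.92	0.02	1	0	1
HMOX1	0.00	0.84	0.98	1	0	0
IL10	0.00	0.49	1.00	1	0	0
IL12A	0.00	0.00	0.00	1	1	1
IL15	0.00	0.00	0.00	1	1	1
IL18	0.00	0.00	0.24	1	1	0
IL1B	0.07	0.00	0.67	0	1	0
IL23A	0.00	0.00	0.00	1	1	1
IL6	1.00	1.00	1.00	0	0	0
IRF4	1.00	0.98	0.99	0	0	0
IRF5	0.00	0.72	0.00	1	0	1
IRF8	0.00	0.00	0.00	1	1	1
ITGAE	1.00	1.00	1.00	0	0	0
ITGAL	0.00	0.83	0.95	1	0	0
ITGAM	0.00	0.00	0.00	1	1	1
ITGAX	0.99	0.86	0.95	0	0	0
LTB	0.99	0.00	0.00	0	1	1
MARCO	0.00	0.00	0.00	1	1	1
MICA	0.98	1.00	0.99	0	0	0
MICB	0.00	0.00	0.00	1	1	1
MMP1	0.00	0.00	0.00	1	1	1
MMP2	1.00	1.00	0.99	0	0	0
MMP3	0.00	0.00	0.00	1	1	1
MMP7	0.34	0.03	0.22	0	1	0
MMP9	1.00	1.00	1.00	0	0	0
MSR1	0.92	0.00	0.00	0	1	1
NFKB1	0.00	0.00	0.00	1	1	1
PTPRC	0.96	0.72	0.95	0	0	0
RAET1E	1.00	0.97	0.99	0	0	0
RAET1G	1.00	1.00	1.00	0	0	0
RAET1L	0.86	0.12	0.67	0	0	0
RARA	0.98	1.00	0.83	0	0	0
RELA	0.00	0.00	0.00	1	1	1
S100A4	0.82	0.95	0.91	0	0	0
SELL	0.97	0.00	0.00	0	1	1
SERPINA1	0.99	0.96	0.99	0	0	0
SERPINB2	0.34	1.00	1.00	0	0	0
SIGLEC10	0.00	0.10	0.70	1	0	0
SIRPA	0.25	0.00	0.01	0	1	1
TIMP1	0.96	0.93	0.90	0	0	0
TLR2	0.85	0.72	0.04	0	0	1
TLR3	1.00	1.00	1.00	0	0	0
TLR4	0.00	0.00	0.00	1	1	1
TLR7	1.00	0.02	1.00	0	1	0
TLR8	0.00	0.00	0.00	1	1	1
TLR9	0.00	0.00	0.00	1	1	1
TNF	0.00	0.00	0.70	1	1	0
TNFSF15	0.83	0.80	0.75	0	0	0
TREM1	0.66	0.00	0.00	0	1	1
TREM2	1.00	1.00	1.00	0	0	0
ULBP3	0.00	0.00	0.00	1	1	1
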