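gene	classical	intermediate	non_classical	p_C_vs_I	p_C_vs_NC	p_I_vs_NC
ACTB	16.3	16.9	16.6	1.4e-09	2.4e-03	4.2e-03
ADAM17	5.9	5.8	6.6	9.5e-01	3.0e-01	2.6e-01
BAX	5.2	7.4	6.4	9.9e-04	8.9e-02	1.2e-01
BCL2	2.6	3	2.5	4.8e-01	8.3e-01	3.6e-01
BCL2L1	0.8	2.4	2.1	3.3e-03	1.8e-02	5.9e-01
C1QA	0.1	2.7	3.1	3.8e-07	5.2e-09	5.9e-01
CCR1	3.6	3.1	1.2	3.6e-01	1.7e-05	4.7e-04
CCR2	1.4	0.4	0	9.5e-03	9.4e-05	4.6e-02
CCR5	0	1	0	1.8e-03	NA	2.3e-03
CCR7	0	0	0	NA	NA	NA
CCR9	0.4	0.1	0.1	1.7e-03	1.7e-02	3.9e-01
CD14	11.7	7.3	4.6	8.8e-17	3.4e-32	7.7e-05
CD163	5.4	1.3	0	1.3e-09	8.3e-19	2.4e-04
CD209	1.1	0.7	0.4	1.2e-01	3.8e-03	2.1e-01
CD33	9.3	8	5.5	1.7e-02	1.5e-09	1.2e-04
CD36	10.3	7.1	1	1.6e-06	1.9e-45	1.0e-18
CD40	6	7.4	5	4.0e-02	1.5e-01	5.3e-04
CD68	14.2	14.9	13.8	4.9e-10	2.4e-01	1.7e-03
CD74	14.9	16.2	14.6	1.3e-16	2.8e-02	2.8e-23
CD93	6.8	5	2.3	5.6e-03	8.1e-12	3.7e-05
CLEC4E	2.2	0.3	0	5.4e-05	1.3e-06	9.7e-02
CSF1R	5.4	10.2	8.9	2.8e-13	3.7e-07	9.7e-03
CST3	13.4	14.3	12.7	3.6e-17	1.6e-02	1.6e-08
CTSB	11.5	12.4	11.1	4.0e-02	5.0e-01	1.8e-03
CTSK	2.5	2.4	1.7	9.6e-01	1.6e-01	1.7e-01
CTSL	0.3	5.2	3.7	1.2e-13	4.8e-09	6.3e-02
CTSS	14.7	14.3	13.8	2.6e-05	1.5e-08	5.0e-04
CX3CR1	5.7	5.1	5	1.9e-01	1.2e-01	7.8e-01
FCGR3A	8.1	11.9	12.3	1.0e-13	3.6e-20	1.5e-01
HLA-DRA	13.2	14.7	12.4	4.0e-15	2.0e-02	1.7e-11
HLA-DRB1	5.4	0.9	2	1.0e-09	2.0e-05	5.3e-02
HMOX1	8.9	12.2	12	3.6e-10	5.0e-08	4.6e-01
IL10	2.4	1.2	0.1	2.3e-02	1.5e-06	1.4e-03
IL12A	5.8	7.6	7	1.6e-03	3.8e-02	3.4e-01
IL15	2.2	2.5	2.9	6.6e-01	2.7e-01	5.0e-01
IL18	2.7	2.9	0.9	7.5e-01	1.8e-03	4.4e-04
IL1B	1.7	3.3	1.1	3.4e-02	2.6e-01	1.8e-03
IL23A	3.3	3.9	3.9	2.2e-01	1.6e-01	1.0e+00
IL6	0	0.1	0.3	3.1e-01	7.5e-02	3.9e-01
IRF4	0.1	0.6	0.6	7.4e-02	1.3e-01	9.1e-01
IRF5	7.1	9.9	8.6	4.2e-07	1.1e-02	6.9e-03
IRF8	6.8	8.1	2.9	6.5e-02	5.2e-08	8.3e-15
ITGAE	0.1	0.3	0.1	4.1e-01	6.2e-01	1.9e-01
ITGAL	7.6	11.4	12	1.7e-10	3.4e-15	2.5e-02
ITGAM	9.8	8.5	2.6	5.2e-02	1.7e-23	1.6e-15
ITGAX	10.5	12.2	11.6	4.9e-09	1.3e-03	6.4e-03
LTB	0.5	2.8	3.4	9.8e-07	7.6e-09	3.5e-01
MARCO	4.3	6.7	2.2	1.3e-03	2.3e-03	2.4e-10
MICA	0.8	0.5	0.8	5.7e-01	9.6e-01	5.2e-01
MICB	3.1	4.7	3.7	1.8e-02	3.4e-01	1.7e-01
MMP1	7.3	7.3	7.5	9.9e-01	7.6e-01	7.8e-01
MMP12	0	0	0	9.2e-01	7.4e-01	8.1e-01
MMP2	0.3	0.7	0.5	8.9e-02	3.2e-01	4.5e-01
MMP3	3.8	6.1	5.7	7.3e-05	7.5e-04	6.1e-01
MMP7	2.5	3.4	2.5	1.4e-02	8.7e-01	9.2e-03
MMP9	0.1	0	0.1	3.2e-01	9.5e-01	3.1e-01
MRC1	0	0	0	NA	NA	NA
MSR1	0.8	3.7	4.4	2.9e-06	1.0e-08	3.6e-01
NFKB1	4.2	5.8	4.1	4.1e-02	9.1e-01	2.9e-02
PTPRC	8.8	11	10	5.4e-34	2.1e-15	1.1e-10
RAET1E	0.1	0.4	0.4	5.2e-05	4.9e-04	4.0e-01
RAET1G	0	0.1	0	1.6e-01	NA	1.6e-01
RAET1L	1.1	2.1	1.5	9.5e-03	3.2e-01	1.4e-01
RARA	11.8	11.8	11.6	8.5e-01	6.2e-01	5.7e-01
RELA	6.4	8.2	5.2	1.7e-02	1.1e-01	4.5e-05
S100A4	13.1	13.8	13.3	1.0e-08	2.7e-01	2.5e-02
SELL	11.9	7.3	2.4	7.9e-15	7.6e-43	4.3e-12
SERPINA1	13.2	13.9	13.1	4.9e-09	7.5e-01	1.4e-02
SERPINB2	0.9	0.1	0	5.0e-03	1.4e-03	3.2e-01
SIGLEC10	4.6	10	10.1	1.5e-15	1.0e-16	9.5e-01
SIRPA	9.4	7.4	4.1	3.2e-04	5.5e-19	1.1e-07
TIMP1	11.7	13	12.2	2.7e-10	1.5e-01	1.2e-02
TLR2	10	9	8.8	1.9e-02	1.4e-02	7.7e-01
TLR3	0	0	0.1	NA	3.1e-01	3.1e-01
TLR4	8.4	8	7.6	4.2e-01	1.5e-01	5.0e-01
TLR7	0.2	1.5	0.5	1.7e-03	3.2e-01	3.1e-02
TLR8	4.7	5.3	5	4.4e-01	6.9e-01	7.1e-01
TLR9	3.8	4.2	4.6	4.3e-01	2.0e-01	6.0e-01
TNF	5.8	8.4	9.8	6.3e-04	8.0e-10	2.9e-02
TNFSF15	5.8	7	6.4	2.4e-05	1.9e-02	4.5e-03
TREM1	11.2	7.8	4.4	1.6e-08	2.4e-18	9.5e-05
TREM2	0.1	0	0	3.2e-01	3.3e-01	NA
ULBP1	0	0	0	NA	NA	NA
ULBP2	0	0	0	NA	3.1e-01	3.1e-01
ULBP3	3.8	5.2	5	3.0e-02	8.2e-02	7.0e-01
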