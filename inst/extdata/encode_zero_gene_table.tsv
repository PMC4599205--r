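gene_id	A1	A2	A3	B1	B2	B3	B4	edger_snr	edger_fdr	voom_snr	voom_fdr
MIPOL1	0.0	0.0	0.0	237.1	232.5	226.0	227.5	45.75	7.47e-31	3.79	3.32e-07
AQP4	0.0	0.0	0.0	46.1	45.0	46.7	44.4	43.87	1.44e-14	3.90	1.99e-06
FAM19A4	0.0	0.0	0.0	142.1	131.1	143.8	131.4	20.21	1.91e-24	4.06	4.72e-07
C17orf66	2.3	2.1	2.1	0.0	0.0	0.0	0.0	16.96	1.89e-02	2.72	7.40e-04
TM4SF19	3.5	3.2	3.2	0.0	0.0	0.0	0.0	16.96	3.00e-03	2.72	2.39e-04
SOX1	0.0	0.0	0.0	7.5	6.7	6.5	6.3	13.02	8.37e-05	4.33	1.27e-04
HPGD	0.0	0.0	0.0	22.6	21.0	19.6	19.0	12.97	5.08e-09	4.56	7.48e-06
LOC100131176	0.0	0.0	0.0	17.9	15.3	18.7	17.2	12.02	5.14e-08	3.51	1.49e-05
ZNF385D	0.0	0.0	0.0	135.5	155.0	155.0	132.3	11.80	2.60e-25	4.67	3.70e-07
NPY1R	0.0	0.0	0.0	209.8	179.9	179.3	208.5	11.38	1.33e-27	2.95	6.77e-07
PLEK	25082.8	12622.5	11394.8	0.0	0.0	0.0	0.0	2.16	1.79e-21	616.11	9.36e-09
MS4A1	25455.1	14937.7	12886.8	0.0	0.0	0.0	0.0	2.63	2.62e-21	57.26	1.60e-08
SLAMF1	7407.2	4859.3	4283.2	0.0	0.0	0.0	0.0	3.32	2.98e-16	55.11	2.53e-08
CCL3	11057.5	3413.1	3544.1	0.0	0.0	0.0	0.0	1.37	4.62e-16	55.13	2.15e-08
FCRLA	7742.0	2979.1	3879.8	0.0	0.0	0.0	0.0	1.92	1.01e-16	16.08	1.84e-08
RGS1	9939.5	9967.3	7741.6	0.0	0.0	0.0	0.0	7.22	4.53e-15	92.66	1.44e-07
DPPA4	0.0	0.0	0.0	14580.2	15215.1	14745.3	10617.3	6.47	2.37e-15	812.02	1.84e-08
TDGF1	0.0	0.0	0.0	15699.8	15481.1	13374.5	8522.5	3.98	6.37e-15	715.48	1.84e-08
SFRP2	0.0	0.0	0.0	14673.3	15229.5	13067.2	7234.4	3.43	1.84e-15	39.87	2.15e-08
BLK	9943.0	2954.7	2351.8	0.0	0.0	0.0	0.0	1.20	2.98e-14	73.28	5.17e-08
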