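100	long	shot	high	400	110	disq	pole	jave	1500
32.00	7.43	15.48	2.27	29.45	26.17	49.28	4.7	61.32	20.08
33.12	7.45	14.97	1.97	30.18	27.39	44.36	5.1	61.76	19.78
32.20	7.44	14.20	1.97	29.82	26.74	43.66	5.2	64.16	20.52
33.90	7.38	15.02	2.03	29.35	26.90	44.80	4.9	64.04	18.94
32.67	7.43	12.92	1.97	30.35	27.50	41.20	5.2	57.46	21.04
33.24	7.72	13.58	2.12	29.79	27.93	43.06	4.9	52.18	19.70
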