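gene	mel	rpe	irid	embryo
ifi30l	6.55	27.16	2138.17	1.23
fhl3	4.64	20.97	1003.29	1.12
slc23l	10.64	9.70	592.05	1.19
gpnmb	1.02	5.28	423.58	1.70
LOC100538040	1.52	9.30	396.38	1.85
LOC100334697	1.06	4.78	330.19	0.09
tpd52l1	5.69	7.75	252.61	1.02
LOC100535932	0.98	4.64	221.28	0.18
pltp	1.07	2.02	145.30	0.02
LOC795494	0.43	2.17	127.94	0.11
LOC100330987	0.56	1.80	99.01	0.01
zgc:77375	0.44	2.24	94.86	0.01
slc25a38a	1.10	1.63	94.77	0.46
LOC100534970	0.65	2.48	81.87	0.18
tmem179bl	0.32	0.66	79.07	0.14
fkbp15	0.55	0.51	32.47	0.31
pcolcel	0.31	0.22	30.46	0.00
si:ch211-38m6.6	0.12	0.23	28.42	0.00
tagln3b	0.13	0.74	24.88	0.06
alx4b	0.10	0.24	24.81	0.08
hsf5	0.05	0.20	21.07	0.00
osbpl10	0.26	0.55	18.67	0.08
si:dkey-225f23.4	0.14	0.13	14.27	0.00
zgc:112054	0.34	0.40	12.99	0.00
slc52a3	0.03	0.12	12.73	0.12
cart1	0.19	0.28	9.87	0.00
myadm	0.14	0.23	7.81	0.00
znf831	0.09	0.10	7.04	0.06
si:ch211-14k19.8	0.06	0.09	5.80	0.00
nfascl	0.07	0.11	5.27	0.00
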