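gene	mel	rpe	irid	embryo
pmela	15177.25	4244.20	148.90	0.57
dct	14134.12	6406.98	402.47	0.65
tyrp1b	12354.09	3769.95	200.99	1.13
tyrp1	2546.87	1474.07	71.46	0.03
rlbp1b	1181.62	1212.86	48.19	0.26
mitfa	1122.44	448.53	16.22	0.00
pah	1081.84	485.25	35.79	23.60
stra6	703.09	539.15	32.81	3.00
rgra	300.56	504.34	27.16	0.21
msnb	254.08	217.35	11.10	0.45
fam213ab	217.86	160.16	12.32	0.28
rbp1a	148.55	137.02	8.74	1.79
slc24a4a	141.08	89.64	7.63	1.26
zgc:114181	122.41	128.26	6.71	0.58
mab21l2	120.20	176.48	2.98	0.82
LOC100004225	105.78	52.37	3.46	1.32
lratl	105.09	96.40	3.52	0.39
oca2	102.56	56.96	1.63	0.07
kif21al_LOC100537698	96.64	104.62	4.16	0.82
dhrs11al	95.71	130.88	6.86	8.45
cadm3	87.46	116.23	4.88	0.12
cdh2	86.69	99.72	6.17	1.10
slc24a5	83.81	34.68	1.56	0.00
s1pr1	83.14	74.37	4.78	1.20
ctgf	62.15	62.19	4.20	0.32
fads6	49.52	84.55	2.76	0.08
foxp4	39.96	84.03	1.78	0.25
foxg1b	39.71	64.02	2.38	0.10
kif21al	37.47	58.20	3.21	0.37
abcg2d	34.72	48.81	1.58	0.00
LOC100149324	33.08	31.15	1.55	0.14
efcab4b	30.89	38.65	1.71	0.00
col11a1a	27.39	27.11	1.22	0.75
rdh13	24.30	31.04	0.81	0.00
cam4l	23.38	37.54	1.34	0.29
srcrb4l	21.14	20.88	1.18	0.80
col4a5	20.86	29.39	1.69	0.49
dao.2	20.27	22.39	1.23	1.39
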