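gene	mel	rpe	irid	embryo
rpl26	22354.26	19692.74	23528.06	87.23
rps17	12677.82	10420.73	16940.17	59.88
rps2	12516.82	9306.57	12379.31	89.39
rpl27a	6506.97	5852.65	8537.27	48.50
slc45a2	4415.88	2376.16	2801.48	0.20
rps26l	2338.29	2362.00	2596.78	23.08
ppp1r21	263.06	227.24	202.38	1.77
crfb5	237.93	329.44	301.82	1.19
LOC100535047	217.00	212.13	135.05	0.40
dhdh	201.46	185.72	161.64	1.52
cyhr1	150.55	157.36	138.95	0.87
igf2bp2b	133.81	97.93	128.56	0.75
ghitm	133.71	119.78	162.37	0.99
her9	126.24	85.17	120.90	0.71
fam168a	89.26	78.21	73.66	0.44
comtb	81.11	55.05	70.61	0.32
fkbp3	75.26	59.48	79.66	0.01
mtbl	65.94	36.58	48.31	0.32
pard3b	53.47	62.57	46.53	0.38
hbp1	41.93	50.61	52.08	0.12
zgc:158345	31.67	43.92	59.38	0.31
ccdc85al	31.26	34.99	40.96	0.13
grma	17.17	18.26	28.83	0.10
mbd2	16.57	16.03	16.31	0.13
triobpl	14.28	16.86	12.85	0.01
rnd2	14.23	10.66	12.26	0.00
LOC100334991	10.17	7.87	10.08	0.03
zgc:136564	5.94	9.00	5.30	0.04
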