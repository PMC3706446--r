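gene	mel	rpe	irid	embryo	p_mel_irid	p_rpe_irid	group
slc2a15a	0.16	0.73	48.55	0.28	7.66E-03	7.89E-03	glucose_transport
pgm2	0.54	0.73	34.00	1.24	4.64E-03	4.68E-03	glycolysis
dera	0.98	0.39	3.67	2.76	3.40E-04	1.55E-04	pentose_phosphate
pfkp	0.63	1.28	12.25	2.42	1.31E-02	1.53E-02	glycolysis
aldoca	0.04	0.00	6.22	0.83	2.50E-03	2.45E-03	glycolysis
gapdhs	191.73	163.31	1605.92	9.03	1.92E-02	1.79E-02	glycolysis
pgk1	146.41	125.46	281.34	38.36	9.05E-03	7.22E-03	glycolysis
pgam1a	216.58	158.84	587.26	32.46	1.13E-03	4.02E-04	glycolysis
eno3	215.46	307.89	1503.93	100.27	4.30E-08	4.09E-05	glycolysis
pkm2a	115.96	97.94	371.83	24.94	4.52E-04	2.83E-04	glycolysis
ldhba	74.53	44.46	440.62	72.72	2.70E-04	2.85E-04	glycolysis
phgdh	371.96	175.60	1538.41	8.25	4.21E-03	2.22E-03	serine_glycine_folate
psat1	7.03	11.92	160.85	7.62	4.68E-03	3.85E-03	serine_glycine_folate
psph	146.30	102.78	2602.05	1.36	1.53E-03	1.38E-03	serine_glycine_folate
shmt2	5.37	5.92	86.02	2.83	9.83E-03	9.50E-03	serine_glycine_folate
mthfd1	7.98	8.41	177.66	13.99	2.71E-02	2.72E-02	serine_glycine_folate
fh	150.18	109.27	562.28	8.65	2.53E-02	1.81E-02	citrate_cycle
mdh1a	388.29	432.95	3948.05	27.33	2.55E-05	1.48E-05	citrate_cycle
pck2	0.10	0.01	1.44	6.09	1.05E-02	8.50E-03	citrate_cycle
aclya	42.29	39.30	106.57	8.19	2.49E-03	1.72E-03	citrate_cycle
rpia	2.49	2.24	11.66	6.52	4.70E-03	3.89E-03	pentose_phosphate
prpsap1	35.48	24.12	95.27	3.13	3.13E-03	1.88E-03	pentose_phosphate
ppat	2.49	3.72	49.23	7.89	4.22E-03	4.26E-03	de_novo_purine
gart	6.41	4.29	167.66	3.46	6.01E-03	5.72E-03	de_novo_purine
pfas	0.53	0.56	34.59	4.53	1.52E-03	1.51E-03	de_novo_purine
paics	57.12	55.35	1465.37	11.68	3.63E-03	3.50E-03	de_novo_purine
adsl	46.06	36.43	805.77	12.45	2.69E-03	2.38E-03	de_novo_purine
atic	7.60	9.63	467.16	18.34	1.01E-02	1.02E-02	de_novo_purine
impdh1b	11.45	21.98	816.19	1.06	1.30E-03	1.21E-03	guanine_branch
gmps	3.86	5.14	102.41	6.35	1.15E-03	1.02E-03	guanine_branch
prtfdc1	1.56	3.10	309.88	0.00	1.39E-03	1.39E-03	purine_salvage
hprt1l	0.25	1.13	21.31	15.99	7.28E-04	6.03E-04	purine_salvage
adssl	1.04	1.75	0.73	6.82	2.61E-01	1.08E-01	adenine_branch
ak1	228.27	149.74	87.12	40.66	4.24E-03	1.75E-01	nucleotide_interconversion
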