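gene	mel	rpe	irid	embryo
syngr2l	86.584	5.728	50.745	1.471
tuba8l3	78.779	11.725	132.465	0.397
pcdh10a	59.639	5.143	54.800	0.423
crestin	16.922	2.214	25.646	0.145
LOC559216	14.652	1.350	27.212	0.689
si:dkey-72l14.7	11.657	1.004	40.247	0.000
cdk15	8.492	0.291	6.475	0.112
emp3l	6.859	0.293	17.644	0.046
lamb1b	5.486	0.630	6.138	0.427
zgc:158328	4.355	0.776	8.553	0.004
opn5	3.824	0.193	1.796	0.000
ppfia2	3.521	0.443	3.859	0.037
rab27bl	3.263	0.278	13.331	0.118
mc1r	2.182	0.076	3.958	0.000
birc7	1.818	0.233	2.960	0.000
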