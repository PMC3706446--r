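gene	mel	rpe	irid	p_mel_rpe	p_mel_irid	p_rpe_irid
gch2	54.25	9.81	1.58	0.007	0.002	0.113
mlphb	187.84	7.96	1.39	0.004	0.003	0.251
kita	3.78	0.39	0.02	0.019	0.011	0.076
pmela	15177.25	4244.20	148.90	0.051	0.011	0.031
dct	14134.12	6406.98	402.47	0.025	0.000	0.028
tyrp1b	12354.09	3769.95	200.99	0.026	0.004	0.009
atic	7.60	9.63	467.16	0.664	0.010	0.010
ednrb1	4.44	1.72	28.63	0.110	0.018	0.013
ltk	0.02	0.20	4.02	0.138	0.002	0.002
sox10	7.57	1.76	13.00	0.010	0.078	0.005
foxd3	3.03	0.35	6.41	0.012	0.237	0.063
snai2	4.26	0.79	4.08	0.016	0.904	0.020
pax6a	10.04	47.48	0.73	0.098	0.004	0.055
nr2e1	0.75	2.41	0.05	0.189	0.041	0.086
myo7ab	1.89	3.32	0.15	0.050	0.001	0.003
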