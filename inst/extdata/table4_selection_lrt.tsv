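species	node	omega_m0	two_dlnl_m3_m0	two_dlnl_m8_m7	m8_omega	beta_p	beta_q	n_beb_sites
AtWRKY	1	0.5712	170.69	17.76	2.78	0.76	1.17	7
AtWRKY	2	0.5689	36.21	6.92	4.68	0.39	0.34	10
AtWRKY	3	0.3248	141.78	8.37	32.95	0.37	0.26	5
AtWRKY	4	0.6485	54.62	9.97	77.65	0.66	1.05	11
AtWRKY	5	0.2682	169.06	10.66	3.32	0.72	0.78	9
CsWRKY	1	0.3331	37.31	1.40e-05	4.28	0.85	1.39	0
CsWRKY	2	0.3623	83.01	8.80e-05	1.00	0.72	1.143	0
CsWRKY	3	0.3081	186.07	2.99e-05	24.88	0.60	0.55	0
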