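locus	chrom	start	end	d_gag	d_pro	d_pol	d_env	age_internal_printed	d_ltr	age_ltr_printed
16p12.3	chr16	19393581	19402152	0.059	0.158	0.206	0.089	64.00	0.082	20.50000
2p12	chr2	82022660	82031279	0.061	0.182	0.204	0.101	68.50	0.070	17.50000
15q21.1	chr15	45234477	45243073	0.051	0.126	0.206	0.099	60.25	0.080	20.00000
8p11.1	chr8	43694016	43702583	0.091	0.177	0.231	0.121	77.50	0.107	26.75000
13q31.1	chr13	84869526	84877320	0.054	NA	0.208	0.103	60.83	NA	NA
4q33	chr4	170126345	170133883	0.058	0.172	0.214	NA	74.00	NA	NA
6p12.3	chr6	48873675	48879725	0.063	NA	NA	0.106	42.25	0.110	27.50000
Yp11.2	chrY	9273707	9279611	0.114	NA	NA	0.139	63.25	0.141	35.25000
8q24.3	chr8	145019974	145032719	NA	NA	0.513	0.093	151.50	NA	NA
Yq11.223	chrY	21580120	21585551	0.105	NA	NA	0.140	61.25	NA	NA
19q13.2	chr19	40954172	40959178	0.075	NA	NA	NA	37.50	0.097	24.25000
Yp11.2	chrY	8121821	8126768	NA	NA	NA	0.125	62.50	0.157	39.25000
Yp11.2	chrY	8996062	9000755	NA	NA	NA	0.133	66.50	NA	NA
Yq11.222	chrY	18622534	18626952	NA	NA	NA	NA	NA	0.194	48.50000
Yq11.223	chrY	21845475	21850069	NA	NA	NA	0.143	71.50	NA	NA
21q21.1	chr21	18563368	18566735	NA	0.266	0.190	NA	114.00	NA	NA
5q33.3	chr5	156660448	156663815	NA	0.215	0.160	NA	93.75	NA	NA
1q22	chr1	155629408	155632775	NA	0.212	0.156	NA	92.00	NA	NA
7q36.1	chr7	150561277	150563994	NA	NA	NA	0.197	98.50	NA	NA
10q24.2	chr10	99822511	99825532	NA	NA	0.169	NA	84.50	NA	NA
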