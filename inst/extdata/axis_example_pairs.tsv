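mirna	pathway	x	n	j	m	p_value	p_adjust
hsa-mir-15a	hsa04010	5	40	10	20000	1.2e-12	5.4e-11
hsa-mir-15a	hsa04151	4	40	10	20000	8.1e-10	1.2e-08
hsa-mir-15a	hsa01521	3	40	10	20000	4.3e-07	2.1e-06
hsa-mir-15b	hsa04010	6	55	10	20000	3.3e-14	4.9e-12
hsa-mir-15b	hsa04151	5	55	10	20000	6.2e-11	1.8e-09
hsa-mir-15b	hsa01521	3	55	10	20000	1.1e-06	4.0e-06
hsa-mir-16	hsa04010	5	48	10	20000	2.9e-12	8.7e-11
hsa-mir-16	hsa04151	4	48	10	20000	1.7e-09	2.5e-08
hsa-mir-16	hsa01521	3	48	10	20000	7.4e-07	3.0e-06
hsa-mir-195	hsa04010	4	35	10	20000	4.4e-10	9.8e-09
hsa-mir-195	hsa04151	4	35	10	20000	4.4e-10	9.8e-09
hsa-mir-195	hsa01521	3	35	10	20000	2.6e-07	1.5e-06
hsa-mir-497	hsa04010	5	42	10	20000	1.6e-12	6.1e-11
hsa-mir-497	hsa04151	4	42	10	20000	1.0e-09	1.9e-08
hsa-mir-497	hsa01521	3	42	10	20000	5.0e-07	2.3e-06
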