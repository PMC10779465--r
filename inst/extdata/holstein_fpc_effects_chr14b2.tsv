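snp1	chr1	pos1	gene1	snp2	chr2	pos2	gene2	effect	log10_inv_p	rank
rs132788949	14	2867641	PTK2	chr31_25156387	31	25156387	blank	-0.0053	46.41	305
rs41624797	14	2929132	PTK2	chr31_25156387	31	25156387	blank	0.0054	48.98	214
rs41624797	14	2929132	PTK2	rs135542379	31	24950173	blank	-0.0051	47.04	283
rs41624797	14	2929132	PTK2	rs41626477	31	9512588	TENM1	0.0048	45.14	365
rs41624797	14	2929132	PTK2	rs110945141	5	36089282	TMEM117	0.0062	44.52	394
rs41624797	14	2929132	PTK2	rs110881559	2	133918945	TAS1R2-PAX7	0.0047	43.90	446
rs55617160	14	3439565	TRAPPC9	chr31_25156387	31	25156387	blank	0.0052	46.41	306
rs55617160	14	3439565	TRAPPC9	rs135542379	31	24950173	blank	-0.0050	45.14	366
rs55617160	14	3439565	TRAPPC9	rs110945141	5	36089282	TMEM117	0.0062	43.90	447
rs55617160	14	3439565	TRAPPC9	rs41626477	31	9512588	TENM1	0.0048	43.90	448
rs135838690	14	3687442	KCNK9	rs42368654	3	3924620	LMX1A (d)	0.0151	45.77	329
rs110822835	14	3710917	KCNK9	rs110945141	5	36089282	TMEM117	0.0062	44.52	395
rs110143087	14	3738219	KCNK9 (d)	rs110945141	5	36089282	TMEM117	0.0065	49.64	192
rs110143087	14	3738219	KCNK9 (d)	rs133552324	10	35535274	GPR176	-0.0071	46.41	307
rs110281272	14	4021974	KCNK9 (d)	rs42477574	5	34302710	SCAF11	-0.0056	45.14	367
rs110281272	14	4021974	KCNK9 (d)	rs136387741	31	87757884	CLCN5	0.0050	45.14	368
rs110281272	14	4021974	KCNK9 (d)	rs136157041	31	87819894	CLCN5 (d)	0.0049	45.14	369
rs110281272	14	4021974	KCNK9 (d)	rs42477555	5	34282642	SCAF11	0.0056	44.52	396
rs110979942	14	4543775	FAM135B	rs109127443	16	16191164	5S-rRNA (d)	-0.0100	44.52	397
rs42306021	14	4858211	FAM135B (d)	rs135542883	31	114523882	blank	0.0073	44.52	398
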