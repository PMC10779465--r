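snp1	chr1	pos1	gene1	snp2	chr2	pos2	gene2	effect	log10_inv_p	rank
rs3423093141	14	2282659	Chr14b1	rs42368654	3	3924620	LMX1A (d)	0.0191	47.69	264
rs3423094258	14	2330431	Chr14b1	rs42368654	3	3924620	LMX1A (d)	-0.0182	55.03	81
rs3423094258	14	2330431	Chr14b1	rs41981850	21	41462728	SCFD1-COCH	-0.0126	45.14	359
rs3423094258	14	2330431	Chr14b1	rs109787816	23	30347149	ZSCAN12	-0.0272	50.30	182
rs3423357679	14	2350879	Chr14b1	rs42368654	3	3924620	LMX1A (d)	0.0178	57.12	50
rs3423357679	14	2350879	Chr14b1	rs41981850	21	41462728	SCFD1-COCH	0.0132	55.03	82
rs3423357679	14	2350879	Chr14b1	rs109787816	23	30347149	ZSCAN12	0.0248	45.14	360
rs3423357679	14	2350879	Chr14b1	rs135435373	31	6923026	bta-mir-2285bj-1 (u)	0.0080	48.33	241
rs136475864	14	2372575	Chr14b1	rs42368654	3	3924620	LMX1A (d)	0.0161	52.97	126
rs134537992	14	2421119	Chr14b1	rs43319812	2	112888145	DOCK10	-0.0136	45.14	361
rs134537992	14	2421119	Chr14b1	rs42368654	3	3924620	LMX1A (d)	0.0187	64.37	5
rs134537992	14	2421119	Chr14b1	rs109376678	8	56181140	TLE4 (d)	-0.0137	45.14	362
rs134537992	14	2421119	Chr14b1	rs109489404	8	56297348	TLE4 (d)	-0.0138	45.77	328
rs134537992	14	2421119	Chr14b1	rs133536911	20	30612345	FGF10 (d)	0.0144	50.30	183
rs134537992	14	2421119	Chr14b1	rs41940594	20	35354207	FYB1-RICTOR	0.0140	48.33	242
rs134537992	14	2421119	Chr14b1	rs41981850	21	41462728	SCFD1-COCH	0.0136	59.25	32
rs134537992	14	2421119	Chr14b1	rs109787816	23	30347149	ZSCAN12	0.0250	46.41	304
rs134537992	14	2421119	Chr14b1	rs109277263	29	41499833	LOC522784	-0.0135	45.14	363
rs134537992	14	2421119	Chr14b1	rs135435373	31	6923026	bta-mir-2285bj-1 (u)	0.0077	45.14	364
rs41661929	14	6113669	Chr14b2	rs136387741	31	87757884	CLCN5	-0.0049	45.77	330
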