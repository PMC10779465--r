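snp1	gene1	snp2	gene2	ac1	aa1	ac2	aa2	ac3	aa3	ac4	aa4
rs134537992	Chr14b1	rs42368654	LMX1A (d)	1_1	0.0124	2_2	0.0001	1_2	-0.0007	2_1	-0.0055
rs3423357679	Chr14b1	rs42368654	LMX1A (d)	1_1	0.0120	2_2	0.0001	1_2	-0.0007	2_1	-0.0050
rs3423094258	Chr14b1	rs42368654	LMX1A (d)	2_1	0.0114	1_2	0.0001	2_2	-0.0008	1_1	-0.0059
rs136475864	Chr14b1	rs42368654	LMX1A (d)	1_1	0.0116	2_2	0.0000	1_2	-0.0006	2_1	-0.0038
rs3423093141	Chr14b1	rs42368654	LMX1A (d)	1_1	0.0150	2_2	0.0001	1_2	-0.0011	2_1	-0.0030
rs135838690	KCNK9	rs42368654	LMX1A (d)	1_1	0.0103	2_2	0.0001	1_2	-0.0005	2_1	-0.0043
rs134537992	Chr14b1	rs41981850	SCFD1-COCH	1_1	0.0094	2_2	0.0001	1_2	-0.0009	2_1	-0.0032
rs3423357679	Chr14b1	rs41981850	SCFD1-COCH	1_1	0.0094	2_2	0.0001	1_2	-0.0009	2_1	-0.0028
rs134537992	Chr14b1	rs133536911	FGF10_U6	1_1	0.0100	2_2	0.0001	1_2	-0.0007	2_1	-0.0037
rs3423094258	Chr14b1	rs109787816	ZSCAN12	2_1	0.0172	1_2	0.0001	2_2	-0.0006	1_1	-0.0094
rs134537992	Chr14b1	rs109787816	ZSCAN12	1_1	0.0162	2_2	0.0001	1_2	-0.0005	2_1	-0.0083
rs110143087	KCNK9 (d)	rs110945141	TMEM117	2_2	0.0037	1_1	0.0004	2_1	-0.0007	1_2	-0.0018
rs134537992	Chr14b1	rs41940594	FYB1_RICTOR	1_1	0.0099	2_2	0.0001	1_2	-0.0007	2_1	-0.0033
rs3423357679	Chr14b1	rs135435373	bta-mir-2285bj-1 (u)	1_1	0.0051	2_2	0.0002	2_1	-0.0010	1_2	-0.0017
rs41624797	PTK2	rs135542379	blank	2_1	0.0016	1_2	0.0007	1_1	-0.0003	2_2	-0.0025
rs110143087	KCNK9 (d)	rs133552324	GPR176	2_1	0.0048	1_2	0.0002	2_2	-0.0006	1_1	-0.0016
rs134537992	Chr14b1	rs109489404	blank	1_2	0.0094	2_1	0.0001	1_1	-0.0008	2_2	-0.0035
rs134539615	ZFAT (d)	rs29016827	STXBP6	1_2	0.0016	2_1	0.0008	1_1	-0.0009	2_2	-0.0015
rs134539615	ZFAT (d)	rs109853041	STXBP6	1_2	0.0016	2_1	0.0009	1_1	-0.0009	2_2	-0.0015
rs41661929	blank	rs136387741	CLCN5	1_2	0.0012	2_1	0.0012	2_2	-0.0008	1_1	-0.0018
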