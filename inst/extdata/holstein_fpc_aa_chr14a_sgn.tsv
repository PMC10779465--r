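snp1	gene1	snp2	gene2	ac1	aa1	ac2	aa2	ac3	aa3	ac4	aa4
rs109146371	PPP1R16A	rs42766480	GC-NPFFR2	1_1	0.0045	2_1	0.0006	2_2	-0.0007	1_2	-0.0030
rs109146371	PPP1R16A	rs110352004	GC-NPFFR2	1_2	0.0034	2_2	0.0003	2_1	-0.0005	1_1	-0.0031
rs110984572	PPP1R16A-FOXH1	rs42766480	GC-NPFFR2	2_1	0.0046	1_1	0.0006	1_2	-0.0007	2_2	-0.0031
rs110984572	PPP1R16A-FOXH1	rs110352004	GC-NPFFR2	2_2	0.0035	1_2	0.0003	1_1	-0.0005	2_1	-0.0032
rs110984572	PPP1R16A-FOXH1	rs109901151	SLC4A4	2_2	0.0034	1_2	0.0003	1_1	-0.0005	2_1	-0.0031
rs137727465	CYHR1	rs42766480	GC-NPFFR2	1_1	0.0046	2_1	0.0006	2_2	-0.0007	1_2	-0.0031
rs137727465	CYHR1	rs110352004	GC-NPFFR2	1_2	0.0035	2_2	0.0003	2_1	-0.0005	1_1	-0.0032
rs137727465	CYHR1	rs109901151	SLC4A4	1_2	0.0034	2_2	0.0003	2_1	-0.0005	1_1	-0.0031
rs137472016	CYHR1-TONSL	rs42766480	GC-NPFFR2	2_1	0.0046	1_1	0.0006	1_2	-0.0007	2_2	-0.0031
rs137472016	CYHR1-TONSL	rs110352004	GC-NPFFR2	2_2	0.0035	1_2	0.0003	1_1	-0.0005	2_1	-0.0032
rs137472016	CYHR1-TONSL	rs109901151	SLC4A4	2_2	0.0034	1_2	0.0003	1_1	-0.0005	2_1	-0.0031
rs211309638	ADCK5-SLC52A2	rs110352004	GC-NPFFR2	2_2	0.0036	1_2	0.0004	1_1	-0.0006	2_1	-0.0034
rs109421300	DGAT1	rs109901151	SLC4A4	1_2	0.0036	2_2	0.0005	2_1	-0.0008	1_1	-0.0032
rs109421300	DGAT1	rs109512265	SLC4A4	1_2	0.0036	2_2	0.0005	2_1	-0.0008	1_1	-0.0033
rs109421300	DGAT1	rs110953922	SLC4A4	1_2	0.0036	2_2	0.0005	2_1	-0.0008	1_1	-0.0033
rs109421300	DGAT1	rs110352004	GC-NPFFR2	1_2	0.0036	2_2	0.0006	2_1	-0.0009	1_1	-0.0033
rs109421300	DGAT1	rs137302420	SLC4A4	1_1	0.0036	2_1	0.0005	2_2	-0.0008	1_2	-0.0033
rs109421300	DGAT1	rs110434046	GC-NPFFR2	1_2	0.0032	2_2	0.0006	2_1	-0.0015	1_1	-0.0039
rs109421300	DGAT1	rs137844449	NPFFR2	1_2	0.0038	2_2	0.0004	2_1	-0.0003	1_1	-0.0018
rs109421300	DGAT1	rs109034709	NPFFR2	1_2	0.0032	2_2	0.0006	2_1	-0.0015	1_1	-0.0038
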