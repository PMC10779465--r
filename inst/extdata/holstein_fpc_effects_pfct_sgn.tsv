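snp1	chr1	pos1	gene1	snp2	chr2	pos2	gene2	effect	log10_inv_p	rank
rs109146371	14	465742	PPP1R16A	rs42766480	6	87156735	GC-NPFFR2	0.0062	67.39	4
rs109146371	14	465742	PPP1R16A	rs110352004	6	87213962	GC-NPFFR2	-0.0058	58.53	35
rs110984572	14	468124	PPP1R16A-FOXH1	rs137302420	6	86751807	SLC4A4	-0.0058	55.72	59
rs110984572	14	468124	PPP1R16A-FOXH1	rs109512265	6	86753255	SLC4A4	0.0058	56.42	53
rs110984572	14	468124	PPP1R16A-FOXH1	rs110953922	6	86755896	SLC4A4	0.0058	56.42	54
rs110984572	14	468124	PPP1R16A-FOXH1	rs109901151	6	86762457	SLC4A4	0.0058	57.82	38
rs110984572	14	468124	PPP1R16A-FOXH1	rs42766480	6	87156735	GC-NPFFR2	-0.0064	70.48	1
rs110984572	14	468124	PPP1R16A-FOXH1	rs110352004	6	87213962	GC-NPFFR2	0.0060	62.15	12
rs137727465	14	487527	CYHR1	rs137302420	6	86751807	SLC4A4	0.0057	55.72	61
rs137727465	14	487527	CYHR1	rs109901151	6	86762457	SLC4A4	-0.0057	57.12	46
rs137727465	14	487527	CYHR1	rs42766480	6	87156735	GC-NPFFR2	0.0063	68.92	3
rs137727465	14	487527	CYHR1	rs110352004	6	87213962	GC-NPFFR2	-0.0059	61.42	21
rs137472016	14	494621	CYHR1-TONSL	rs137302420	6	86751807	SLC4A4	-0.0058	55.72	66
rs137472016	14	494621	CYHR1-TONSL	rs109512265	6	86753255	SLC4A4	0.0058	56.42	55
rs137472016	14	494621	CYHR1-TONSL	rs110953922	6	86755896	SLC4A4	0.0058	56.42	56
rs137472016	14	494621	CYHR1-TONSL	rs109901151	6	86762457	SLC4A4	0.0058	57.82	40
rs137472016	14	494621	CYHR1-TONSL	rs42766480	6	87156735	GC-NPFFR2	-0.0064	69.70	2
rs137472016	14	494621	CYHR1-TONSL	rs110352004	6	87213962	GC-NPFFR2	0.0060	61.42	22
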