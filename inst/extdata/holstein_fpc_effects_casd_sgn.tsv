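snp1	chr1	pos1	gene1	snp2	chr2	pos2	gene2	effect	log10_inv_p	rank
rs134432442	14	550784	CPSF1	rs137302420	6	86751807	SLC4A4	-0.0056	50.30	178
rs134432442	14	550784	CPSF1	rs109512265	6	86753255	SLC4A4	0.0056	50.96	164
rs134432442	14	550784	CPSF1	rs110953922	6	86755896	SLC4A4	0.0056	50.96	165
rs134432442	14	550784	CPSF1	rs109901151	6	86762457	SLC4A4	0.0055	51.63	153
rs134432442	14	550784	CPSF1	rs110352004	6	87213962	GC-NPFFR2	0.0055	51.63	154
rs211309638	14	572120	ADCK5-SLC52A2	rs137302420	6	86751807	SLC4A4	-0.0059	55.72	68
rs211309638	14	572120	ADCK5-SLC52A2	rs109512265	6	86753255	SLC4A4	0.0059	56.42	57
rs211309638	14	572120	ADCK5-SLC52A2	rs110953922	6	86755896	SLC4A4	0.0059	56.42	58
rs211309638	14	572120	ADCK5-SLC52A2	rs109901151	6	86762457	SLC4A4	0.0059	57.12	49
rs211309638	14	572120	ADCK5-SLC52A2	rs110352004	6	87213962	GC-NPFFR2	0.0060	58.53	37
rs109421300	14	609870	DGAT1	rs137302420	6	86751807	SLC4A4	0.0055	49.64	191
rs109421300	14	609870	DGAT1	rs109512265	6	86753255	SLC4A4	-0.0056	50.30	179
rs109421300	14	609870	DGAT1	rs110953922	6	86755896	SLC4A4	-0.0055	50.30	180
rs109421300	14	609870	DGAT1	rs109901151	6	86762457	SLC4A4	-0.0055	50.96	166
rs109421300	14	609870	DGAT1	rs110352004	6	87213962	GC-NPFFR2	-0.0055	50.30	181
rs135549651	14	775260	SMPD5	rs137302420	6	86751807	SLC4A4	-0.0054	48.33	240
rs135549651	14	775260	SMPD5	rs109512265	6	86753255	SLC4A4	0.0054	48.98	211
rs135549651	14	775260	SMPD5	rs110953922	6	86755896	SLC4A4	0.0054	48.98	212
rs135549651	14	775260	SMPD5	rs109901151	6	86762457	SLC4A4	0.0053	48.98	213
rs135549651	14	775260	SMPD5	rs110352004	6	87213962	GC-NPFFR2	0.0051	44.52	393
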