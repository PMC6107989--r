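type	description	begin	end	length	accession	entryName	taxid	order
CHAIN	NF-kappa-B p105 subunit	1	968	967	P19838	NFKB1_HUMAN	9606	1
CHAIN	NF-kappa-B p50 subunit	1	433	432	P19838	NFKB1_HUMAN	9606	1
DOMAIN	RHD	42	367	325	P19838	NFKB1_HUMAN	9606	1
DOMAIN	Death	800	890	90	P19838	NFKB1_HUMAN	9606	1
REPEAT	ANK 1	540	570	30	P19838	NFKB1_HUMAN	9606	1
REPEAT	ANK 2	577	607	30	P19838	NFKB1_HUMAN	9606	1
REPEAT	ANK 3	611	641	30	P19838	NFKB1_HUMAN	9606	1
MOTIF	Nuclear localization signal	360	363	3	P19838	NFKB1_HUMAN	9606	1
MOD_RES	Phosphoserine	337	337	0	P19838	NFKB1_HUMAN	9606	1
MOD_RES	Phosphoserine; by IKK	932	932	0	P19838	NFKB1_HUMAN	9606	1
CHAIN	NF-kappa-B p100 subunit	1	900	899	Q00653	NFKB2_HUMAN	9606	2
CHAIN	NF-kappa-B p52 subunit	1	454	453	Q00653	NFKB2_HUMAN	9606	2
DOMAIN	RHD	38	342	304	Q00653	NFKB2_HUMAN	9606	2
DOMAIN	Death	760	850	90	Q00653	NFKB2_HUMAN	9606	2
REPEAT	ANK 1	490	520	30	Q00653	NFKB2_HUMAN	9606	2
REPEAT	ANK 2	527	557	30	Q00653	NFKB2_HUMAN	9606	2
REPEAT	ANK 3	561	591	30	Q00653	NFKB2_HUMAN	9606	2
MOD_RES	Phosphoserine; by IKK	866	866	0	Q00653	NFKB2_HUMAN	9606	2
CHAIN	Transcription factor RelB	1	579	578	Q01201	RELB_HUMAN	9606	3
DOMAIN	RHD	125	418	293	Q01201	RELB_HUMAN	9606	3
MOD_RES	Phosphothreonine	84	84	0	Q01201	RELB_HUMAN	9606	3
MOD_RES	Phosphoserine	552	552	0	Q01201	RELB_HUMAN	9606	3
CHAIN	Proto-oncogene c-Rel	1	587	586	Q04864	REL_HUMAN	9606	4
DOMAIN	RHD	8	297	289	Q04864	REL_HUMAN	9606	4
MOTIF	Nuclear localization signal	290	293	3	Q04864	REL_HUMAN	9606	4
MOD_RES	Phosphoserine	503	503	0	Q04864	REL_HUMAN	9606	4
CHAIN	Transcription factor p65	1	551	550	Q04206	TF65_HUMAN	9606	5
DOMAIN	RHD	19	306	287	Q04206	TF65_HUMAN	9606	5
REGION	Activation domain	415	459	44	Q04206	TF65_HUMAN	9606	5
MOTIF	Nuclear localization signal	301	304	3	Q04206	TF65_HUMAN	9606	5
REGION	Transactivation domain	536	544	8	Q04206	TF65_HUMAN	9606	5
MOD_RES	N-acetylmethionine	1	1	0	Q04206	TF65_HUMAN	9606	5
MOD_RES	Phosphoserine	38	38	0	Q04206	TF65_HUMAN	9606	5
MOD_RES	Phosphoserine; by PKA	38	38	0	Q04206	TF65_HUMAN	9606	5
MOD_RES	Phosphoserine; by CK1	122	122	0	Q04206	TF65_HUMAN	9606	5
MOD_RES	Phosphothreonine	123	123	0	Q04206	TF65_HUMAN	9606	5
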