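type	description	begin	end	length	accession	entryName	taxid	order
CHAIN	Transcription factor p65	1	551	550	Q04206	TF65_HUMAN	9606	1
DOMAIN	RHD	19	306	287	Q04206	TF65_HUMAN	9606	1
REGION	Activation domain	415	459	44	Q04206	TF65_HUMAN	9606	1
MOTIF	Nuclear localization signal	301	304	3	Q04206	TF65_HUMAN	9606	1
REGION	Transactivation domain	536	544	8	Q04206	TF65_HUMAN	9606	1
MOD_RES	N-acetylmethionine	1	1	0	Q04206	TF65_HUMAN	9606	1
MOD_RES	Phosphoserine	38	38	0	Q04206	TF65_HUMAN	9606	1
MOD_RES	Phosphoserine; by PKA	38	38	0	Q04206	TF65_HUMAN	9606	1
MOD_RES	Phosphoserine; by CK1	122	122	0	Q04206	TF65_HUMAN	9606	1
MOD_RES	Phosphothreonine	123	123	0	Q04206	TF65_HUMAN	9606	1
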