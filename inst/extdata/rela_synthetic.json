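[
  {
    "accession": "Q04206",
    "entryName": "TF65_HUMAN",
    "taxid": 9606,
    "features": [
      {
        "type": "CHAIN",
        "category": "UNSPECIFIED",
        "description": "Transcription factor p65",
        "begin": "1",
        "end": "551"
      },
      {
        "type": "DOMAIN",
        "category": "UNSPECIFIED",
        "description": "RHD",
        "begin": "19",
        "end": "306"
      },
      {
        "type": "REGION",
        "category": "UNSPECIFIED",
        "description": "Activation domain",
        "begin": "415",
        "end": "459"
      },
      {
        "type": "MOTIF",
        "category": "UNSPECIFIED",
        "description": "Nuclear localization signal",
        "begin": "301",
        "end": "304"
      },
      {
        "type": "REGION",
        "category": "UNSPECIFIED",
        "description": "Transactivation domain",
        "begin": "536",
        "end": "544"
      },
      {
        "type": "MOD_RES",
        "category": "UNSPECIFIED",
        "description": "N-acetylmethionine",
        "begin": "1",
        "end": "1"
      },
      {
        "type": "MOD_RES",
        "category": "UNSPECIFIED",
        "description": "Phosphoserine",
        "begin": "38",
        "end": "38"
      },
      {
        "type": "MOD_RES",
        "category": "UNSPECIFIED",
        "description": "Phosphoserine; by PKA",
        "begin": "38",
        "end": "38"
      },
      {
        "type": "MOD_RES",
        "category": "UNSPECIFIED",
        "description": "Phosphoserine; by CK1",
        "begin": "122",
        "end": "122"
      },
      {
        "type": "MOD_RES",
        "category": "UNSPECIFIED",
        "description": "Phosphothreonine",
        "begin": "123",
        "end": "123"
      }
    ]
  }
]
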