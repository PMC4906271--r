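[
  {"id": "UbxCore", "tf": "Ubx", "iupac": "TAAT",
   "note": "Hox homeodomain core"},
  {"id": "UbxSite", "tf": "Ubx", "iupac": "ATAATS",
   "note": "extended Ubx site, S = G or C"},
  {"id": "Adf1", "tf": "Adf-1", "iupac": "TGGCTGCCGTCGCGAT",
   "note": "Adf-1 recognition sequence from the fly vg quadrant enhancer"},
  {"id": "MAD1_fly", "tf": "MAD1", "iupac": "GCCGTCGC",
   "note": "MAD1 site nested inside the Adf-1 sequence"},
  {"id": "MAD1_bee", "tf": "MAD1", "iupac": "GCTGCCCGCCGC",
   "note": "MAD1 site form found in the bee vg quadrant enhancer"},
  {"id": "GAF", "tf": "GAF", "iupac": "GAGAG",
   "note": "GAGA factor repeat"}
]
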