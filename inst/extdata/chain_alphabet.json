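[
  {"label": "C2",   "carbons": 2,  "branch": "n"},
  {"label": "C3",   "carbons": 3,  "branch": "n"},
  {"label": "C4",   "carbons": 4,  "branch": "n"},
  {"label": "iC5",  "carbons": 5,  "branch": "i"},
  {"label": "aiC5", "carbons": 5,  "branch": "ai"},
  {"label": "iC6",  "carbons": 6,  "branch": "i"},
  {"label": "aiC6", "carbons": 6,  "branch": "ai"},
  {"label": "C8",   "carbons": 8,  "branch": "n"},
  {"label": "nC10", "carbons": 10, "branch": "n"},
  {"label": "iC10", "carbons": 10, "branch": "i"},
  {"label": "nC11", "carbons": 11, "branch": "n"},
  {"label": "nC12", "carbons": 12, "branch": "n"}
]
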