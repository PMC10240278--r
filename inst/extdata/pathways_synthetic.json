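[
  {
    "name": "De novo triacylglycerol biosynthesis",
    "nodes": [
      {"id": "G3P", "type": "compound"},
      {"id": "FA", "type": "compound"},
      {"id": "LPA", "type": "compound"},
      {"id": "PA", "type": "compound"},
      {"id": "DG", "type": "compound"},
      {"id": "TG", "type": "compound"},
      {"id": "gpat", "type": "reaction"},
      {"id": "agpat", "type": "reaction"},
      {"id": "pap", "type": "reaction"},
      {"id": "dgat", "type": "reaction"}
    ],
    "edges": [
      ["G3P", "gpat"], ["FA", "gpat"], ["gpat", "LPA"],
      ["LPA", "agpat"], ["FA", "agpat"], ["agpat", "PA"],
      ["PA", "pap"], ["pap", "DG"],
      ["DG", "dgat"], ["FA", "dgat"], ["dgat", "TG"]
    ]
  },
  {
    "name": "Phospholipid biosynthesis",
    "nodes": [
      {"id": "PA", "type": "compound"},
      {"id": "CDP_DG", "type": "compound"},
      {"id": "DG", "type": "compound"},
      {"id": "PC", "type": "compound"},
      {"id": "PE", "type": "compound"},
      {"id": "PS", "type": "compound"},
      {"id": "LPE", "type": "compound"},
      {"id": "Choline", "type": "compound"},
      {"id": "Ethanolamine", "type": "compound"},
      {"id": "cds", "type": "reaction"},
      {"id": "pap2", "type": "reaction"},
      {"id": "cept", "type": "reaction"},
      {"id": "ept", "type": "reaction"},
      {"id": "pss", "type": "reaction"},
      {"id": "psd", "type": "reaction"},
      {"id": "pla2g", "type": "reaction"}
    ],
    "edges": [
      ["PA", "cds"], ["cds", "CDP_DG"],
      ["PA", "pap2"], ["pap2", "DG"],
      ["DG", "cept"], ["Choline", "cept"], ["cept", "PC"],
      ["DG", "ept"], ["Ethanolamine", "ept"], ["ept", "PE"],
      ["PE", "pss"], ["pss", "PS"],
      ["PS", "psd"], ["psd", "PE"],
      ["PE", "pla2g"], ["pla2g", "LPE"]
    ]
  },
  {
    "name": "Cardiolipin biosynthesis",
    "nodes": [
      {"id": "PA", "type": "compound"},
      {"id": "CDP_DG", "type": "compound"},
      {"id": "G3P", "type": "compound"},
      {"id": "PGP", "type": "compound"},
      {"id": "PG", "type": "compound"},
      {"id": "CL", "type": "compound"},
      {"id": "cds2", "type": "reaction"},
      {"id": "pgps", "type": "reaction"},
      {"id": "pgpp", "type": "reaction"},
      {"id": "cls", "type": "reaction"}
    ],
    "edges": [
      ["PA", "cds2"], ["cds2", "CDP_DG"],
      ["CDP_DG", "pgps"], ["G3P", "pgps"], ["pgps", "PGP"],
      ["PGP", "pgpp"], ["pgpp", "PG"],
      ["PG", "cls"], ["CDP_DG", "cls"], ["cls", "CL"]
    ]
  },
  {
    "name": "Sphingolipid biosynthesis",
    "nodes": [
      {"id": "Serine", "type": "compound"},
      {"id": "FA", "type": "compound"},
      {"id": "Sph", "type": "compound"},
      {"id": "Cer", "type": "compound"},
      {"id": "SM", "type": "compound"},
      {"id": "PC", "type": "compound"},
      {"id": "DG", "type": "compound"},
      {"id": "spt", "type": "reaction"},
      {"id": "cers", "type": "reaction"},
      {"id": "sms", "type": "reaction"}
    ],
    "edges": [
      ["Serine", "spt"], ["FA", "spt"], ["spt", "Sph"],
      ["Sph", "cers"], ["FA", "cers"], ["cers", "Cer"],
      ["Cer", "sms"], ["PC", "sms"], ["sms", "SM"], ["sms", "DG"]
    ]
  },
  {
    "name": "Phosphatidylinositol metabolism",
    "nodes": [
      {"id": "CDP_DG", "type": "compound"},
      {"id": "Inositol", "type": "compound"},
      {"id": "PI", "type": "compound"},
      {"id": "DG", "type": "compound"},
      {"id": "pis", "type": "reaction"},
      {"id": "plc", "type": "reaction"}
    ],
    "edges": [
      ["CDP_DG", "pis"], ["Inositol", "pis"], ["pis", "PI"],
      ["PI", "plc"], ["plc", "DG"]
    ]
  },
  {
    "name": "Inositol metabolism",
    "nodes": [
      {"id": "G6P", "type": "compound"},
      {"id": "Ins1P", "type": "compound"},
      {"id": "Inositol", "type": "compound"},
      {"id": "PI", "type": "compound"},
      {"id": "ino1", "type": "reaction"},
      {"id": "impase", "type": "reaction"},
      {"id": "pis2", "type": "reaction"}
    ],
    "edges": [
      ["G6P", "ino1"], ["ino1", "Ins1P"],
      ["Ins1P", "impase"], ["impase", "Inositol"],
      ["Inositol", "pis2"], ["pis2", "PI"]
    ]
  },
  {
    "name": "Arachidonic acid metabolism",
    "nodes": [
      {"id": "PC", "type": "compound"},
      {"id": "LPC", "type": "compound"},
      {"id": "FA", "type": "compound"},
      {"id": "PGH2", "type": "compound"},
      {"id": "PGE2", "type": "compound"},
      {"id": "pla2", "type": "reaction"},
      {"id": "cox", "type": "reaction"},
      {"id": "pges", "type": "reaction"}
    ],
    "edges": [
      ["PC", "pla2"], ["pla2", "FA"], ["pla2", "LPC"],
      ["FA", "cox"], ["cox", "PGH2"],
      ["PGH2", "pges"], ["pges", "PGE2"]
    ]
  },
  {
    "name": "Alpha-linolenic acid metabolism",
    "nodes": [
      {"id": "PC", "type": "compound"},
      {"id": "FA", "type": "compound"},
      {"id": "EPA", "type": "compound"},
      {"id": "pla2b", "type": "reaction"},
      {"id": "elovl", "type": "reaction"}
    ],
    "edges": [
      ["PC", "pla2b"], ["pla2b", "FA"],
      ["FA", "elovl"], ["elovl", "EPA"]
    ]
  },
  {
    "name": "Linoleic acid metabolism",
    "nodes": [
      {"id": "PC", "type": "compound"},
      {"id": "FA", "type": "compound"},
      {"id": "HODE", "type": "compound"},
      {"id": "pla2c", "type": "reaction"},
      {"id": "lox15", "type": "reaction"}
    ],
    "edges": [
      ["PC", "pla2c"], ["pla2c", "FA"],
      ["FA", "lox15"], ["lox15", "HODE"]
    ]
  },
  {
    "name": "Leukotriene biosynthesis",
    "nodes": [
      {"id": "FA", "type": "compound"},
      {"id": "LTA4", "type": "compound"},
      {"id": "LTB4", "type": "compound"},
      {"id": "LTC4", "type": "compound"},
      {"id": "lo5", "type": "reaction"},
      {"id": "ltah", "type": "reaction"},
      {"id": "ltcs", "type": "reaction"}
    ],
    "edges": [
      ["FA", "lo5"], ["lo5", "LTA4"],
      ["LTA4", "ltah"], ["ltah", "LTB4"],
      ["LTA4", "ltcs"], ["ltcs", "LTC4"]
    ]
  },
  {
    "name": "Steroid biosynthesis",
    "nodes": [
      {"id": "Acetyl_CoA", "type": "compound"},
      {"id": "HMG_CoA", "type": "compound"},
      {"id": "Mevalonate", "type": "compound"},
      {"id": "Squalene", "type": "compound"},
      {"id": "Cholesterol", "type": "compound"},
      {"id": "hmgs", "type": "reaction"},
      {"id": "hmgr", "type": "reaction"},
      {"id": "sqs", "type": "reaction"},
      {"id": "cyp51", "type": "reaction"}
    ],
    "edges": [
      ["Acetyl_CoA", "hmgs"], ["hmgs", "HMG_CoA"],
      ["HMG_CoA", "hmgr"], ["hmgr", "Mevalonate"],
      ["Mevalonate", "sqs"], ["sqs", "Squalene"],
      ["Squalene", "cyp51"], ["cyp51", "Cholesterol"]
    ]
  },
  {
    "name": "Bile acid biosynthesis",
    "nodes": [
      {"id": "Cholesterol", "type": "compound"},
      {"id": "C7aOH_Chol", "type": "compound"},
      {"id": "CA", "type": "compound"},
      {"id": "cyp7a1", "type": "reaction"},
      {"id": "steps", "type": "reaction"}
    ],
    "edges": [
      ["Cholesterol", "cyp7a1"], ["cyp7a1", "C7aOH_Chol"],
      ["C7aOH_Chol", "steps"], ["steps", "CA"]
    ]
  }
]
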