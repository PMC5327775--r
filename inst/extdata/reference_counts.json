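{
  "version": 1,
  "description": "Aggregate strategy-1 risk-label combination counts and per-system strategy-2 marginals for the published 95-patient imatinib-treated CML reference cohort (62 achieving MMR, 33 not).",
  "systems": ["sokal", "hasford", "eutos", "elts"],
  "combination_rows": [
    {"sokal": "lowish", "hasford": "lowish", "eutos": "lowish", "elts": "lowish", "n_mmr": 43, "n_no_mmr": 19},
    {"sokal": "lowish", "hasford": "lowish", "eutos": "lowish", "elts": "high",   "n_mmr": 5,  "n_no_mmr": 2},
    {"sokal": "lowish", "hasford": "lowish", "eutos": "high",   "elts": "lowish", "n_mmr": 0,  "n_no_mmr": 0},
    {"sokal": "lowish", "hasford": "lowish", "eutos": "high",   "elts": "high",   "n_mmr": 0,  "n_no_mmr": 1},
    {"sokal": "lowish", "hasford": "high",   "eutos": "lowish", "elts": "lowish", "n_mmr": 0,  "n_no_mmr": 0},
    {"sokal": "lowish", "hasford": "high",   "eutos": "lowish", "elts": "high",   "n_mmr": 0,  "n_no_mmr": 0},
    {"sokal": "lowish", "hasford": "high",   "eutos": "high",   "elts": "lowish", "n_mmr": 0,  "n_no_mmr": 0},
    {"sokal": "lowish", "hasford": "high",   "eutos": "high",   "elts": "high",   "n_mmr": 0,  "n_no_mmr": 0},
    {"sokal": "high",   "hasford": "lowish", "eutos": "lowish", "elts": "lowish", "n_mmr": 7,  "n_no_mmr": 5},
    {"sokal": "high",   "hasford": "lowish", "eutos": "lowish", "elts": "high",   "n_mmr": 0,  "n_no_mmr": 1},
    {"sokal": "high",   "hasford": "lowish", "eutos": "high",   "elts": "lowish", "n_mmr": 1,  "n_no_mmr": 1},
    {"sokal": "high",   "hasford": "lowish", "eutos": "high",   "elts": "high",   "n_mmr": 4,  "n_no_mmr": 0},
    {"sokal": "high",   "hasford": "high",   "eutos": "lowish", "elts": "lowish", "n_mmr": 1,  "n_no_mmr": 1},
    {"sokal": "high",   "hasford": "high",   "eutos": "lowish", "elts": "high",   "n_mmr": 0,  "n_no_mmr": 1},
    {"sokal": "high",   "hasford": "high",   "eutos": "high",   "elts": "lowish", "n_mmr": 0,  "n_no_mmr": 0},
    {"sokal": "high",   "hasford": "high",   "eutos": "high",   "elts": "high",   "n_mmr": 1,  "n_no_mmr": 2}
  ],
  "strategy2_high_marginals": {
    "sokal":   {"n_no_mmr": 23, "n_mmr": 39},
    "hasford": {"n_no_mmr": 20, "n_mmr": 26},
    "eutos":   {"n_no_mmr": 4,  "n_mmr": 6},
    "elts":    {"n_no_mmr": 19, "n_mmr": 23}
  }
}
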