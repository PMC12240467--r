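{
  "id": "diamond_toy",
  "metabolites": [
    {"id": "A_c", "compartment": "c"},
    {"id": "B_c", "compartment": "c"},
    {"id": "C_c", "compartment": "c"}
  ],
  "reactions": [
    {
      "id": "R_up",
      "metabolites": {"A_c": 1.0},
      "lower_bound": 0, "upper_bound": 10,
      "gene_reaction_rule": ""
    },
    {
      "id": "R_a1",
      "metabolites": {"A_c": -1.0, "B_c": 1.0},
      "lower_bound": 0, "upper_bound": 1000,
      "gene_reaction_rule": "g1"
    },
    {
      "id": "R_a2",
      "metabolites": {"A_c": -1.0, "B_c": 1.0},
      "lower_bound": 0, "upper_bound": 1000,
      "gene_reaction_rule": "g2 and g3"
    },
    {
      "id": "R_b",
      "metabolites": {"B_c": -1.0, "C_c": 1.0},
      "lower_bound": 0, "upper_bound": 1000,
      "gene_reaction_rule": "g4 or g5"
    },
    {
      "id": "R_bio",
      "metabolites": {"C_c": -1.0},
      "lower_bound": 0, "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 1.0
    }
  ],
  "genes": [
    {"id": "g1"}, {"id": "g2"}, {"id": "g3"}, {"id": "g4"}, {"id": "g5"}
  ]
}
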