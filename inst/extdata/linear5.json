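{
  "id": "linear5",
  "metabolites": [
    {
      "id": "A"
    },
    {
      "id": "B"
    },
    {
      "id": "C"
    },
    {
      "id": "D"
    }
  ],
  "reactions": [
    {
      "id": "EX_A",
      "metabolites": {
        "A": -1
      },
      "lower_bound": 0,
      "upper_bound": 100,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "R1",
      "metabolites": {
        "A": -1,
        "B": 1
      },
      "lower_bound": 0,
      "upper_bound": 10,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "R2",
      "metabolites": {
        "B": -1,
        "C": 1,
        "D": 1
      },
      "lower_bound": 0,
      "upper_bound": 10,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "BIOMASS",
      "metabolites": {
        "C": -1
      },
      "lower_bound": 0,
      "upper_bound": 100,
      "gene_reaction_rule": "",
      "objective_coefficient": 1
    },
    {
      "id": "EX_D",
      "metabolites": {
        "D": -1
      },
      "lower_bound": 0,
      "upper_bound": 100,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    }
  ],
  "biomass_reaction": "BIOMASS",
  "core_nutrients": [],
  "metadata": {
    "id": "linear5",
    "carbon_source": "A"
  }
}
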