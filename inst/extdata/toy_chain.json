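{
  "compartments": {
    "c": "cytosol"
  },
  "metabolites": [
    {
      "id": "A_c",
      "name": "A",
      "compartment": "c"
    },
    {
      "id": "B_c",
      "name": "B",
      "compartment": "c"
    },
    {
      "id": "C_c",
      "name": "C",
      "compartment": "c"
    },
    {
      "id": "D_c",
      "name": "D",
      "compartment": "c"
    }
  ],
  "reactions": [
    {
      "id": "EX_A",
      "name": "EX_A",
      "stoichiometry": {
        "A_c": -1
      },
      "lower_bound": -10,
      "upper_bound": 0
    },
    {
      "id": "AtoB",
      "name": "AtoB",
      "stoichiometry": {
        "A_c": -1,
        "B_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000
    },
    {
      "id": "BtoC",
      "name": "BtoC",
      "stoichiometry": {
        "B_c": -1,
        "C_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000
    },
    {
      "id": "CtoD",
      "name": "CtoD",
      "stoichiometry": {
        "C_c": -1,
        "D_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000
    },
    {
      "id": "EX_D",
      "name": "EX_D",
      "stoichiometry": {
        "D_c": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000
    }
  ],
  "biomass_reaction": "EX_D",
  "objective_sense": "maximize"
}
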