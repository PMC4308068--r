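{
  "metabolites": ["G", "E", "X", "M", "N", "B"],
  "reactions": [
    {
      "id": "EX_GLC",
      "stoich": {
        "G": -1
      },
      "lb": -10,
      "ub": 0,
      "genes": []
    },
    {
      "id": "EX_ETH",
      "stoich": {
        "E": -1
      },
      "lb": 0,
      "ub": 0,
      "genes": []
    },
    {
      "id": "R_GM",
      "stoich": {
        "G": -1,
        "M": 1
      },
      "lb": 0,
      "ub": 1000,
      "genes": []
    },
    {
      "id": "R_EX",
      "stoich": {
        "E": -2,
        "X": 1
      },
      "lb": 0,
      "ub": 1000,
      "genes": "g3"
    },
    {
      "id": "R_XM",
      "stoich": {
        "X": -1,
        "M": 1
      },
      "lb": 0,
      "ub": 1000,
      "genes": "g4"
    },
    {
      "id": "R_MN",
      "stoich": {
        "M": -1,
        "N": 1
      },
      "lb": 0,
      "ub": 1000,
      "genes": "g1"
    },
    {
      "id": "R_NB",
      "stoich": {
        "N": -1,
        "B": 1
      },
      "lb": 0,
      "ub": 1000,
      "genes": "g2"
    },
    {
      "id": "BIOMASS",
      "stoich": {
        "B": -1
      },
      "lb": 0,
      "ub": 1000,
      "genes": []
    }
  ],
  "objective": "BIOMASS"
}
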