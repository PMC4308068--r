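{
  "metabolites": ["A", "B", "C"],
  "reactions": [
    {
      "id": "EX_A",
      "stoich": {
        "A": -1
      },
      "lb": -10,
      "ub": 0,
      "genes": []
    },
    {
      "id": "R1",
      "stoich": {
        "A": -1,
        "B": 1
      },
      "lb": 0,
      "ub": 1000,
      "genes": ["g1", "g2"]
    },
    {
      "id": "R2",
      "stoich": {
        "B": -1,
        "C": 1
      },
      "lb": 0,
      "ub": 1000,
      "genes": []
    },
    {
      "id": "BIOMASS",
      "stoich": {
        "C": -1
      },
      "lb": 0,
      "ub": 1000,
      "genes": []
    }
  ],
  "objective": "BIOMASS"
}
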