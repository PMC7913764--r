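{
  "frc_cm3": 3300,
  "generations": [
    {
      "generation": 1,
      "region": "bronchial",
      "diameter_cm": 1.5887,
      "length_cm": 10.591,
      "gsd": 1.15,
      "branch_min_deg": 0,
      "branch_max_deg": 0,
      "gravity_min_deg": 0,
      "gravity_max_deg": 90
    },
    {
      "generation": 2,
      "region": "bronchial",
      "diameter_cm": 1.0768,
      "length_cm": 4.2011,
      "gsd": 1.15,
      "branch_min_deg": 15,
      "branch_max_deg": 60,
      "gravity_min_deg": 0,
      "gravity_max_deg": 90
    },
    {
      "generation": 3,
      "region": "bronchial",
      "diameter_cm": 0.7325,
      "length_cm": 1.6769,
      "gsd": 1.15,
      "branch_min_deg": 15,
      "branch_max_deg": 60,
      "gravity_min_deg": 0,
      "gravity_max_deg": 90
    },
    {
      "generation": 4,
      "region": "bronchial",
      "diameter_cm": 0.4942,
      "length_cm": 1.1209,
      "gsd": 1.15,
      "branch_min_deg": 15,
      "branch_max_deg": 60,
      "gravity_min_deg": 0,
      "gravity_max_deg": 90
    },
    {
      "generation": 5,
      "region": "bronchial",
      "diameter_cm": 0.3972,
      "length_cm": 0.9444,
      "gsd": 1.15,
      "branch_min_deg": 15,
      "branch_max_deg": 60,
      "gravity_min_deg": 0,
      "gravity_max_deg": 90
    },
    {
      "generation": 6,
      "region": "bronchial",
      "diameter_cm": 0.3089,
      "length_cm": 0.7943,
      "gsd": 1.15,
      "branch_min_deg": 15,
      "branch_max_deg": 60,
      "gravity_min_deg": 0,
      "gravity_max_deg": 90
    },
    {
      "generation": 7,
      "region": "bronchial",
      "diameter_cm": 0.2471,
      "length_cm": 0.6708,
      "gsd": 1.15,
      "branch_min_deg": 15,
      "branch_max_deg": 60,
      "gravity_min_deg": 0,
      "gravity_max_deg": 90
    },
    {
      "generation": 8,
      "region": "bronchial",
      "diameter_cm": 0.203,
      "length_cm": 0.6708,
      "gsd": 1.15,
      "branch_min_deg": 15,
      "branch_max_deg": 60,
      "gravity_min_deg": 0,
      "gravity_max_deg": 90
    },
    {
      "generation": 9,
      "region": "bronchial",
      "diameter_cm": 0.1642,
      "length_cm": 0.5649,
      "gsd": 1.15,
      "branch_min_deg": 15,
      "branch_max_deg": 60,
      "gravity_min_deg": 0,
      "gravity_max_deg": 90
    },
    {
      "generation": 10,
      "region": "bronchial",
      "diameter_cm": 0.1359,
      "length_cm": 0.4766,
      "gsd": 1.15,
      "branch_min_deg": 15,
      "branch_max_deg": 60,
      "gravity_min_deg": 0,
      "gravity_max_deg": 90
    },
    {
      "generation": 11,
      "region": "bronchial",
      "diameter_cm": 0.1147,
      "length_cm": 0.406,
      "gsd": 1.15,
      "branch_min_deg": 15,
      "branch_max_deg": 60,
      "gravity_min_deg": 0,
      "gravity_max_deg": 90
    },
    {
      "generation": 12,
      "region": "bronchial",
      "diameter_cm": 0.0962,
      "length_cm": 0.3442,
      "gsd": 1.15,
      "branch_min_deg": 15,
      "branch_max_deg": 60,
      "gravity_min_deg": 0,
      "gravity_max_deg": 90
    },
    {
      "generation": 13,
      "region": "bronchial",
      "diameter_cm": 0.0838,
      "length_cm": 0.2913,
      "gsd": 1.15,
      "branch_min_deg": 15,
      "branch_max_deg": 60,
      "gravity_min_deg": 0,
      "gravity_max_deg": 90
    },
    {
      "generation": 14,
      "region": "bronchial",
      "diameter_cm": 0.0724,
      "length_cm": 0.2383,
      "gsd": 1.15,
      "branch_min_deg": 15,
      "branch_max_deg": 60,
      "gravity_min_deg": 0,
      "gravity_max_deg": 90
    },
    {
      "generation": 15,
      "region": "bronchial",
      "diameter_cm": 0.0653,
      "length_cm": 0.203,
      "gsd": 1.15,
      "branch_min_deg": 15,
      "branch_max_deg": 60,
      "gravity_min_deg": 0,
      "gravity_max_deg": 90
    },
    {
      "generation": 16,
      "region": "bronchial",
      "diameter_cm": 0.0583,
      "length_cm": 0.1765,
      "gsd": 1.15,
      "branch_min_deg": 15,
      "branch_max_deg": 60,
      "gravity_min_deg": 0,
      "gravity_max_deg": 90
    },
    {
      "generation": 17,
      "region": "acinar",
      "diameter_cm": 0.053,
      "length_cm": 0.1456,
      "gsd": 1.1,
      "branch_min_deg": 15,
      "branch_max_deg": 60,
      "gravity_min_deg": 0,
      "gravity_max_deg": 90
    },
    {
      "generation": 18,
      "region": "acinar",
      "diameter_cm": 0.0477,
      "length_cm": 0.1244,
      "gsd": 1.1,
      "branch_min_deg": 15,
      "branch_max_deg": 60,
      "gravity_min_deg": 0,
      "gravity_max_deg": 90
    },
    {
      "generation": 19,
      "region": "acinar",
      "diameter_cm": 0.0441,
      "length_cm": 0.1033,
      "gsd": 1.1,
      "branch_min_deg": 15,
      "branch_max_deg": 60,
      "gravity_min_deg": 0,
      "gravity_max_deg": 90
    },
    {
      "generation": 20,
      "region": "acinar",
      "diameter_cm": 0.0415,
      "length_cm": 0.0874,
      "gsd": 1.1,
      "branch_min_deg": 15,
      "branch_max_deg": 60,
      "gravity_min_deg": 0,
      "gravity_max_deg": 90
    },
    {
      "generation": 21,
      "region": "acinar",
      "diameter_cm": 0.0397,
      "length_cm": 0.0733,
      "gsd": 1.1,
      "branch_min_deg": 15,
      "branch_max_deg": 60,
      "gravity_min_deg": 0,
      "gravity_max_deg": 90
    },
    {
      "generation": 22,
      "region": "acinar",
      "diameter_cm": 0.038,
      "length_cm": 0.0618,
      "gsd": 1.1,
      "branch_min_deg": 15,
      "branch_max_deg": 60,
      "gravity_min_deg": 0,
      "gravity_max_deg": 90
    },
    {
      "generation": 23,
      "region": "acinar",
      "diameter_cm": 0.0362,
      "length_cm": 0.0521,
      "gsd": 1.1,
      "branch_min_deg": 15,
      "branch_max_deg": 60,
      "gravity_min_deg": 0,
      "gravity_max_deg": 90
    },
    {
      "generation": 24,
      "region": "acinar",
      "diameter_cm": 0.0362,
      "length_cm": 0.0441,
      "gsd": 1.1,
      "branch_min_deg": 15,
      "branch_max_deg": 60,
      "gravity_min_deg": 0,
      "gravity_max_deg": 90
    }
  ]
}
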