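{
  "strategies": {
    "intervention": {
      "name": "TMZ + SoC",
      "transition_matrix": [
        [0.946564885496183, 0.0419847328244275, 0.0114503816793893, 0],
        [0.527173913043478, 0.41304347826087, 0.0543478260869565, 0.00543478260869565],
        [0.194174757281553, 0.611650485436893, 0.155339805825243, 0.0388349514563107],
        [0.142857142857143, 0.180952380952381, 0.247619047619048, 0.428571428571429]
      ],
      "monthly_drug_cost": 29.18,
      "row_ess": [262, 184, 103, 105]
    },
    "comparator": {
      "name": "SoC",
      "transition_matrix": [
        [0.906077348066298, 0.0939226519337017, 0, 0],
        [0.465968586387435, 0.418848167539267, 0.0942408376963351, 0.0209424083769634],
        [0.258426966292135, 0.438202247191011, 0.235955056179775, 0.0674157303370786],
        [0.1171875, 0.265625, 0.15625, 0.4609375]
      ],
      "monthly_drug_cost": 23.4,
      "row_ess": [181, 191, 89, 128]
    }
  },
  "mortality": {
    "minimal": 0.046,
    "mild": 0.048,
    "moderate": 0.081,
    "severe": 0.109
  },
  "utilities": {
    "minimal": 0.81,
    "mild": 0.75,
    "moderate": 0.6,
    "severe": 0.39
  },
  "baseline": {
    "minimal": 0,
    "mild": 0.469387755102041,
    "moderate": 0.262755102040816,
    "severe": 0.267857142857143
  },
  "costs": {
    "outpatient_visits": {
      "minimal": 8,
      "mild": 15.75,
      "moderate": 39.88,
      "severe": 76.5
    },
    "diagnostic_tests": {
      "minimal": 41.62,
      "mild": 62.05,
      "moderate": 101,
      "severe": 122.37
    },
    "laboratory_tests": {
      "minimal": 20.41,
      "mild": 25.63,
      "moderate": 45.31,
      "severe": 61.24
    },
    "hosp_no_revasc": {
      "minimal": 4.67,
      "mild": 35.03,
      "moderate": 331.06,
      "severe": 1428.63
    },
    "hosp_revasc": {
      "minimal": 586.24,
      "mild": 683.62,
      "moderate": 1583.23,
      "severe": 1972.77
    }
  },
  "settings": {
    "n_cycles": 4,
    "cycle_length_years": 0.25,
    "wtp_threshold": 34000,
    "discount_rate": 0,
    "currency": "EUR",
    "price_year": 2016
  }
}
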