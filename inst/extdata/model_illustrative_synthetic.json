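{
  "metadata": {
    "name": "illustrative-nonlab-cvd",
    "vintage": "synthetic"
  },
  "submodels": {
    "female": {
      "coronary": {
        "coefficients": {
          "age": 0.07,
          "smoker": 0.45,
          "sbp": 0.016,
          "bmi": 0.035
        },
        "centring": {
          "age": 55,
          "sbp": 130,
          "bmi": 23.5
        },
        "reference_risk": 0.0582354664157513
      },
      "stroke": {
        "coefficients": {
          "age": 0.08,
          "smoker": 0.25,
          "sbp": 0.022,
          "bmi": 0.02
        },
        "centring": {
          "age": 55,
          "sbp": 130,
          "bmi": 23.5
        },
        "reference_risk": 0.0996754774137344
      }
    },
    "male": {
      "coronary": {
        "coefficients": {
          "age": 0.07,
          "smoker": 0.45,
          "sbp": 0.016,
          "bmi": 0.035
        },
        "centring": {
          "age": 55,
          "sbp": 130,
          "bmi": 23.5
        },
        "reference_risk": 0.0535148520465161
      },
      "stroke": {
        "coefficients": {
          "age": 0.08,
          "smoker": 0.25,
          "sbp": 0.022,
          "bmi": 0.02
        },
        "centring": {
          "age": 55,
          "sbp": 130,
          "bmi": 23.5
        },
        "reference_risk": 0.104165864703472
      }
    }
  }
}
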