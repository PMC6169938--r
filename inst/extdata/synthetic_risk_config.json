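{
  "hazards": {
    "age_start": [35, 40, 45, 50, 55, 60, 65, 70, 75, 80, 85],
    "age_end": [40, 45, 50, 55, 60, 65, 70, 75, 80, 85, 90],
    "incidence": [0.000961121223189623, 0.00138271073882296, 0.00158239115915285, 0.00206291192567539, 0.00259931929279833, 0.00285738364105522, 0.00316235372967198, 0.00357069241075643, 0.00357069241075643, 0.00421596265590943, 0.00443879538243703],
    "competing_mortality": [0.00211504199489202, 0.00243522738010357, 0.00377201458478346, 0.00461109773516075, 0.0055326119925437, 0.00732286720381831, 0.00981243502850358, 0.011957927176169, 0.0157074117500821, 0.0194071037245827, 0.0272736144530249]
  },
  "log_rr": {
    "n_first_degree_relatives": {
      "0": 0,
      "1": 0.45,
      "2+": 0.9
    },
    "age_menarche": {
      ">=14": 0,
      "12-13": 0.1,
      "<12": 0.21
    },
    "age_first_birth": {
      "<20": 0,
      "20-24": 0.12,
      "25-29": 0.21,
      ">=30": 0.29,
      "nulliparous": 0.29
    },
    "n_biopsies": {
      "0": 0,
      "1": 0.46,
      "2+": 0.62
    },
    "hyperplasia": {
      "no": 0,
      "yes": 0.93
    }
  },
  "age_split": 50
}
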