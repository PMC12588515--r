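{
  "settings": {
    "discount_rate": 0.03,
    "wtp_threshold": 160000,
    "exchange_rate": 0.02877,
    "cost_to_charge_ratio": 1.63,
    "charge_direction": "charge_over_cost",
    "start_age": 55,
    "max_age": 100,
    "cycle_length": 1,
    "gni_per_capita": 249600,
    "cpi_index": {
      "2019": 100.4,
      "2020": 99.5,
      "2021": 100.7,
      "2022": 106.8,
      "2023": 108.1
    },
    "psa_row_n": 60
  },
  "mask_allowed": ["CAPD->CAPD", "CAPD_ICO->CAPD", "APD->CAPD", "CAPD->CAPD_ICO", "CAPD_ICO->CAPD_ICO", "APD->CAPD_ICO", "CAPD->APD", "CAPD_ICO->APD", "APD->APD", "CAPD->HD", "CAPD_ICO->HD", "APD->HD", "HD->HD", "CAPD->KT", "CAPD_ICO->KT", "APD->KT", "HD->KT", "KT->KT", "CAPD->DEATH", "CAPD_ICO->DEATH", "APD->DEATH", "HD->DEATH", "KT->DEATH", "DEATH->DEATH"],
  "steady_derived": true,
  "tables": {
    "transitions": "transitions.csv",
    "costs": "costs.csv",
    "utilities": "utilities.csv",
    "uncertainty": "uncertainty.csv"
  }
}
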