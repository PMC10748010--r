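{
  "paclitaxel_vanhasselt": {
    "drug": "paclitaxel", "study": "van Hasselt 2014",
    "cmax": 2.2, "auc": 8.7, "cl": 35.7, "units": "mg/L",
    "n": 5, "gw": 23
  },
  "paclitaxel_janssen": {
    "drug": "paclitaxel", "study": "Janssen 2021",
    "cmax": 3.3, "auc": 8.0, "cl": 39.2, "units": "mg/L",
    "n": 20, "gw": 31
  },
  "docetaxel_vanhasselt": {
    "drug": "docetaxel", "study": "van Hasselt 2014",
    "cmax": 1.7, "auc": 2.4, "cl": 75, "units": "mg/L",
    "n": 3, "gw": 32
  },
  "docetaxel_janssen": {
    "drug": "docetaxel", "study": "Janssen 2021",
    "cmax": 1.7, "auc": 2.3, "cl": 79, "units": "mg/L",
    "n": 9, "gw": 32
  },
  "acalabrutinib_byrd": {
    "drug": "acalabrutinib", "study": "Byrd 2016",
    "cmax": 827, "auc": 1850, "units": "ng/mL",
    "population": "non-pregnant patients with cancer"
  }
}
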