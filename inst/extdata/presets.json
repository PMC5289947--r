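{
  "WT_A20A": {
    "genotype": "WT", "paradigm": "A20A",
    "a1": 0.4023, "r": 0.8128, "b": 0.0760,
    "provenance": "closed-form inversion of reported wild-type A20A group mean percentages (double-positive 32.7, nucleus-only 4.54, cytoplasm-only 7.53)"
  },
  "TS_A20A": {
    "genotype": "TS65DN", "paradigm": "A20A",
    "a1": 0.2820, "r": 0.7730, "b": 0.1536,
    "provenance": "closed-form inversion of reported Ts65Dn A20A group mean percentages (double-positive 21.8, nucleus-only 11.03, cytoplasm-only 6.40)"
  },
  "WT_ASAC": {
    "genotype": "WT", "paradigm": "ASAC",
    "a1": 0.3905,
    "provenance": "reported wild-type single-exploration nuclear percentage 39.05"
  },
  "TS_ASAC": {
    "genotype": "TS65DN", "paradigm": "ASAC",
    "a1": 0.2086,
    "provenance": "reported Ts65Dn single-exploration nuclear percentage 20.86"
  },
  "WT_CC": {
    "genotype": "WT", "paradigm": "CC",
    "f0": 0.0689,
    "provenance": "reported wild-type caged-control nuclear percentage 6.89"
  },
  "TS_CC": {
    "genotype": "TS65DN", "paradigm": "CC",
    "f0": 0.0679,
    "provenance": "reported Ts65Dn caged-control nuclear percentage 6.79"
  },
  "WT_AX4_A20A": {
    "genotype": "WT", "paradigm": "AX4_A20A",
    "a1": 0.3262, "r": 0.8305, "b": 0.1036,
    "provenance": "inversion of reported wild-type repeated-exposure means (double-positive 27.09, nucleus-only 6.98); cytoplasm-only 5.53 derived by subtraction from the reported total Arc-positive 39.6"
  },
  "TS_AX4_A20A": {
    "genotype": "TS65DN", "paradigm": "AX4_A20A",
    "a1": 0.2290, "r": 0.6092, "b": 0.2233,
    "provenance": "inversion of reported Ts65Dn repeated-exposure means (double-positive 13.95, nucleus-only 17.22); cytoplasm-only 8.95 derived by subtraction from the reported total Arc-positive 40.12"
  }
}
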