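{
  "clonogenic": {
    "alpha": 0.2,
    "beta": 0.0243395251005119,
    "rbe_beam": 3,
    "gamma_fraction": 0.35,
    "nitrogen_share": 0.4,
    "cbe": {
      "dpa_bstpg": 8.43,
      "bpa": 3.8,
      "bsh": 2.41
    },
    "uptake_ug_per_1e9": {
      "dpa_bstpg": 60.3,
      "bpa": 11.9,
      "bsh": 3
    },
    "dpa_iso_target_gy": 0.88,
    "durations_min": [
      10,
      20,
      30
    ],
    "xray_doses_gy": [
      1.5,
      3,
      4.5,
      6,
      7.5,
      9
    ],
    "control_colonies": 200,
    "replicates": 3
  },
  "biodistribution": [
    {
      "compound": "dpa_bstpg",
      "route": "ced",
      "time_h": 2.5,
      "n": 6,
      "organ": "tumor",
      "mean": 45,
      "sd": 18.8
    },
    {
      "compound": "dpa_bstpg",
      "route": "ced",
      "time_h": 2.5,
      "n": 6,
      "organ": "brain",
      "mean": 0.8,
      "sd": 0.8
    },
    {
      "compound": "dpa_bstpg",
      "route": "ced",
      "time_h": 2.5,
      "n": 6,
      "organ": "blood",
      "mean": 0.4,
      "sd": 0.2
    },
    {
      "compound": "dpa_bstpg",
      "route": "ced",
      "time_h": 12,
      "n": 4,
      "organ": "tumor",
      "mean": 32.5,
      "sd": 13.1
    },
    {
      "compound": "dpa_bstpg",
      "route": "ced",
      "time_h": 12,
      "n": 4,
      "organ": "brain",
      "mean": 0.8,
      "sd": 0.8
    },
    {
      "compound": "dpa_bstpg",
      "route": "ced",
      "time_h": 12,
      "n": 4,
      "organ": "blood",
      "mean": 0.3,
      "sd": 0.1
    },
    {
      "compound": "dpa_bstpg",
      "route": "ced",
      "time_h": 24,
      "n": 4,
      "organ": "tumor",
      "mean": 23.7,
      "sd": 13.5
    },
    {
      "compound": "dpa_bstpg",
      "route": "ced",
      "time_h": 24,
      "n": 4,
      "organ": "brain",
      "mean": 1,
      "sd": 1.4
    },
    {
      "compound": "dpa_bstpg",
      "route": "ced",
      "time_h": 24,
      "n": 4,
      "organ": "blood",
      "mean": 0.4,
      "sd": 0.1
    },
    {
      "compound": "bpa",
      "route": "iv",
      "time_h": 2.5,
      "n": 4,
      "organ": "tumor",
      "mean": 20.6,
      "sd": 2.2
    },
    {
      "compound": "bpa",
      "route": "iv",
      "time_h": 2.5,
      "n": 4,
      "organ": "brain",
      "mean": 5.5,
      "sd": 0.6
    },
    {
      "compound": "bpa",
      "route": "iv",
      "time_h": 2.5,
      "n": 4,
      "organ": "blood",
      "mean": 7.7,
      "sd": 0.5
    },
    {
      "compound": "bpa",
      "route": "iv",
      "time_h": 12,
      "n": 4,
      "organ": "tumor",
      "mean": 9.1,
      "sd": 3.3
    },
    {
      "compound": "bpa",
      "route": "iv",
      "time_h": 12,
      "n": 4,
      "organ": "brain",
      "mean": 2.5,
      "sd": 0.6
    },
    {
      "compound": "bpa",
      "route": "iv",
      "time_h": 12,
      "n": 4,
      "organ": "blood",
      "mean": 2.9,
      "sd": 0.4
    },
    {
      "compound": "bpa",
      "route": "iv",
      "time_h": 24,
      "n": 4,
      "organ": "tumor",
      "mean": 8.2,
      "sd": 0.8
    },
    {
      "compound": "bpa",
      "route": "iv",
      "time_h": 24,
      "n": 4,
      "organ": "brain",
      "mean": 2.3,
      "sd": 0.3
    },
    {
      "compound": "bpa",
      "route": "iv",
      "time_h": 24,
      "n": 4,
      "organ": "blood",
      "mean": 2.9,
      "sd": 0.4
    },
    {
      "compound": "combination",
      "route": "combination",
      "time_h": 2.5,
      "n": 4,
      "organ": "tumor",
      "mean": 61.8,
      "sd": 20.4
    },
    {
      "compound": "combination",
      "route": "combination",
      "time_h": 2.5,
      "n": 4,
      "organ": "brain",
      "mean": 5.1,
      "sd": 0.7
    },
    {
      "compound": "combination",
      "route": "combination",
      "time_h": 2.5,
      "n": 4,
      "organ": "blood",
      "mean": 7.3,
      "sd": 0.5
    }
  ],
  "uptake": [
    {
      "cell_line": "F98",
      "compound": "dpa_bstpg",
      "mean": 60.3,
      "sd": 3.8,
      "n": 3
    },
    {
      "cell_line": "F98",
      "compound": "bpa",
      "mean": 11.9,
      "sd": 0.5,
      "n": 3
    },
    {
      "cell_line": "F98",
      "compound": "bsh",
      "mean": 3,
      "sd": 0.2,
      "n": 3
    },
    {
      "cell_line": "C6",
      "compound": "dpa_bstpg",
      "mean": 26,
      "sd": 2.4,
      "n": 3
    },
    {
      "cell_line": "C6",
      "compound": "bpa",
      "mean": 6.5,
      "sd": 0.2,
      "n": 3
    },
    {
      "cell_line": "C6",
      "compound": "bsh",
      "mean": 3.2,
      "sd": 0.1,
      "n": 3
    },
    {
      "cell_line": "9L",
      "compound": "dpa_bstpg",
      "mean": 24,
      "sd": 4,
      "n": 3
    },
    {
      "cell_line": "9L",
      "compound": "bpa",
      "mean": 24.3,
      "sd": 1.7,
      "n": 3
    },
    {
      "cell_line": "9L",
      "compound": "bsh",
      "mean": 5.3,
      "sd": 0.4,
      "n": 3
    }
  ],
  "expression": {
    "folds": [
      13.95,
      23.07,
      11.09
    ],
    "ref_ct": 20,
    "dct_normal": 4,
    "ct_noise_sd": 0
  },
  "survival": {
    "arms": [
      {
        "arm": "Untreated",
        "median_days": 21,
        "n": 6
      },
      {
        "arm": "Neutron only",
        "median_days": 23,
        "n": 5
      },
      {
        "arm": "DPA-BSTPG-BNCT",
        "median_days": 28,
        "n": 6
      },
      {
        "arm": "BPA-BNCT",
        "median_days": 31.5,
        "n": 5
      },
      {
        "arm": "Combination BNCT",
        "median_days": 33.5,
        "n": 6
      }
    ],
    "shape": 25
  },
  "beam": {
    "thermal_fluence": 800000000000,
    "d_h_gy": 0.180672,
    "d_gamma_gy": 0.6
  },
  "dose_table": {
    "nitrogen_pct": 2.2,
    "rbe": 3,
    "ced_fraction": 0.268,
    "arms": [
      {
        "arm": "Untreated",
        "beam_on": false,
        "tissues": {
          "brain": {
            "boron_conc": 0
          },
          "tumor": {
            "boron_conc": 0
          }
        }
      },
      {
        "arm": "Neutron only",
        "beam_on": true,
        "tissues": {
          "brain": {
            "boron_conc": 0
          },
          "tumor": {
            "boron_conc": 0
          }
        }
      },
      {
        "arm": "DPA-BSTPG-BNCT",
        "beam_on": true,
        "tissues": {
          "brain": {
            "boron_conc": 0.8,
            "ced": true
          },
          "tumor": {
            "boron_conc": 45,
            "ced": true,
            "cbe": 8.43
          }
        }
      },
      {
        "arm": "BPA-BNCT",
        "beam_on": true,
        "tissues": {
          "brain": {
            "boron_conc": 5.5,
            "cbe": 1.35
          },
          "tumor": {
            "boron_conc": 20.6,
            "cbe": 3.8
          }
        }
      }
    ]
  }
}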