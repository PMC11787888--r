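{
  "config_version": 1,
  "description": "Murine one-compartment PK parameters, human-simulated dosing regimens, unbound fractions and human reference exposures for meropenem, cefiderocol and tobramycin in the standardized neutropenic murine pneumonia model.",
  "drugs": {
    "meropenem": {
      "class": "beta_lactam",
      "human_regimen": "2 g every 8 h as a 3 h infusion",
      "unbound_fraction": { "mouse": 0.92, "human": 0.98 },
      "matrices": {
        "plasma": {
          "volume_L_kg": 0.04,
          "ka_per_h": 1.34,
          "kel_per_h": 27.13,
          "regimen": {
            "times_h": [0, 1.25, 3.5, 6],
            "amounts_mg_kg": [65, 65, 45, 45],
            "repeat_interval_h": 8,
            "horizon_h": 24
          }
        },
        "ELF": {
          "volume_L_kg": 1.6,
          "ka_per_h": 7.0,
          "kel_per_h": 2.5,
          "regimen": {
            "times_h": [0, 1.25, 3.5, 4.75, 6],
            "amounts_mg_kg": [20, 50, 30, 20, 15],
            "repeat_interval_h": 8,
            "horizon_h": 24
          }
        }
      },
      "human_reference": {
        "plasma": {
          "ft_above": {
            "mic_mg_L": [1, 2, 4, 8, 16, 32, 64, 128],
            "pct": [100, 100, 100, 78, 50, 19, 0, 0]
          }
        },
        "ELF": {
          "ft_above": {
            "mic_mg_L": [1, 2, 4, 8, 16, 32, 64, 128],
            "pct": [90, 71, 50, 16, 0, 0, 0, 0]
          }
        }
      }
    },
    "cefiderocol": {
      "class": "beta_lactam",
      "human_regimen": "2 g every 8 h as a 3 h infusion",
      "unbound_fraction": { "mouse": 0.684, "human": 0.42 },
      "matrices": {
        "plasma": {
          "volume_L_kg": 0.19,
          "ka_per_h": 21.71,
          "kel_per_h": 0.74,
          "regimen": {
            "times_h": [0, 1, 2, 4, 6],
            "amounts_mg_kg": [5, 7.5, 10, 3.5, 1],
            "repeat_interval_h": 8,
            "horizon_h": 24
          }
        },
        "ELF": {
          "volume_L_kg": 0.33,
          "ka_per_h": 1.94,
          "kel_per_h": 0.72,
          "regimen": {
            "times_h": [0, 1, 2, 4, 6],
            "amounts_mg_kg": [3.75, 5, 6.25, 1.75, 1],
            "repeat_interval_h": 8,
            "horizon_h": 24
          }
        }
      },
      "human_reference": {
        "plasma": {
          "ft_above": {
            "mic_mg_L": [1, 2, 4, 8, 16, 32, 64, 128],
            "pct": [100, 99, 98, 76, 48, 11, 0, 0]
          }
        },
        "ELF": null
      }
    },
    "tobramycin": {
      "class": "aminoglycoside",
      "human_regimen": "7 mg/kg as a 30 min infusion",
      "unbound_fraction": { "mouse": 0.776, "human": 0.9 },
      "matrices": {
        "plasma": {
          "volume_L_kg": 0.37,
          "ka_per_h": 23.68,
          "kel_per_h": 0.31,
          "regimen": {
            "times_h": [0, 3, 6, 9],
            "amounts_mg_kg": [9, 4, 2, 0.5],
            "repeat_interval_h": null,
            "horizon_h": 24
          }
        },
        "ELF": {
          "volume_L_kg": 0.79,
          "ka_per_h": 1.74,
          "kel_per_h": 0.35,
          "regimen": {
            "times_h": [0, 1.5, 3, 4.5, 6.5, 9, 12.5, 16],
            "amounts_mg_kg": [4.8, 3.6, 2.4, 2.4, 2.7, 2.4, 1.2, 1.2],
            "repeat_interval_h": null,
            "horizon_h": 24
          }
        }
      },
      "human_reference": {
        "plasma": { "fcmax_mg_L": 18.3, "fauc_mg_h_L": 103 },
        "ELF": { "fcmax_mg_L": 6.8, "fauc_mg_h_L": 79 }
      }
    }
  },
  "penetration": {
    "tobramycin_human_elf": {
      "slope_per_h": 0.1223,
      "intercept": 0.1567,
      "r_squared": 0.986,
      "fitted_times_h": [0.5, 2, 4, 8],
      "auc_ratio_reference": 0.69
    }
  }
}
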