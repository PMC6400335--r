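{
  "schema_version": 1,
  "horizon_days": 90,
  "n_trials": 50,
  "base_seed": 1,
  "cycles_per_day": 96,
  "multi_morbidity": false,
  "uncomplicated_pct": 86.95,
  "uncomplicated_entry_plan": "normal_delivery",
  "shifts": [
    {
      "name": "morning",
      "start_cycle": 24,
      "nurses": 5,
      "doctors": 3,
      "admission_prob": 0.4
    },
    {
      "name": "evening",
      "start_cycle": 56,
      "nurses": 3,
      "doctors": 2,
      "admission_prob": 0.28
    },
    {
      "name": "night",
      "start_cycle": 88,
      "nurses": 3,
      "doctors": 1,
      "admission_prob": 0.625
    }
  ],
  "complications": [
    {
      "name": "postpartum_haemorrhage",
      "incidence_pct": 4,
      "severity_mean": 0.02,
      "smo_mortality": 0.17,
      "severity_sd": 0.075,
      "deterioration_rate": 150,
      "entry_plan": "pph_acute",
      "illustrative": true
    },
    {
      "name": "preeclampsia",
      "incidence_pct": 4.5,
      "severity_mean": 0.005,
      "smo_mortality": 0.17,
      "severity_sd": 0.0825,
      "deterioration_rate": 400,
      "entry_plan": "pec_acute",
      "illustrative": true
    },
    {
      "name": "eclampsia",
      "incidence_pct": 1.5,
      "severity_mean": 0.04,
      "smo_mortality": 0.17,
      "severity_sd": 0.065,
      "deterioration_rate": 100,
      "entry_plan": "ecl_acute",
      "illustrative": true
    },
    {
      "name": "uterine_rupture",
      "incidence_pct": 1,
      "severity_mean": 0.1,
      "smo_mortality": 0.17,
      "severity_sd": 0.035,
      "deterioration_rate": 60,
      "entry_plan": "rup_surgical",
      "illustrative": true
    },
    {
      "name": "sepsis",
      "incidence_pct": 2.05,
      "severity_mean": 0.07,
      "smo_mortality": 0.17,
      "severity_sd": 0.05,
      "deterioration_rate": 250,
      "entry_plan": "sep_acute",
      "illustrative": true
    }
  ],
  "plans": [
    {
      "id": "normal_delivery",
      "duration": 4,
      "efficacy": 0,
      "successor": "postnatal_recovery",
      "nurse_count": 1,
      "nurse_every": 1,
      "nurse_hold": true,
      "doctor_count": 0,
      "doctor_every": 1,
      "doctor_hold": false,
      "drugs": {
        "oxytocin": {
          "dose": 0.1,
          "every": 4
        }
      }
    },
    {
      "id": "postnatal_recovery",
      "duration": 76,
      "efficacy": 0,
      "successor": null,
      "nurse_count": 1,
      "nurse_every": 38,
      "nurse_hold": false,
      "doctor_count": 1,
      "doctor_every": 76,
      "doctor_hold": false,
      "drugs": []
    },
    {
      "id": "pph_acute",
      "duration": 8,
      "efficacy": 0.124302805465515,
      "successor": "pph_recovery",
      "nurse_count": 2,
      "nurse_every": 1,
      "nurse_hold": true,
      "doctor_count": 1,
      "doctor_every": 4,
      "doctor_hold": false,
      "drugs": {
        "oxytocin": {
          "dose": 0.2,
          "every": 2
        }
      }
    },
    {
      "id": "pph_recovery",
      "duration": 136,
      "efficacy": 0.124302805465515,
      "successor": null,
      "nurse_count": 1,
      "nurse_every": 12,
      "nurse_hold": false,
      "doctor_count": 1,
      "doctor_every": 48,
      "doctor_hold": false,
      "drugs": []
    },
    {
      "id": "pec_acute",
      "duration": 48,
      "efficacy": 0.0881966197443437,
      "successor": "pec_recovery",
      "nurse_count": 1,
      "nurse_every": 8,
      "nurse_hold": false,
      "doctor_count": 1,
      "doctor_every": 24,
      "doctor_hold": false,
      "drugs": {
        "hydralazine": {
          "dose": 0.03,
          "every": 12
        }
      }
    },
    {
      "id": "pec_recovery",
      "duration": 144,
      "efficacy": 0.0881966197443437,
      "successor": null,
      "nurse_count": 1,
      "nurse_every": 24,
      "nurse_hold": false,
      "doctor_count": 1,
      "doctor_every": 72,
      "doctor_hold": false,
      "drugs": {
        "hydralazine": {
          "dose": 0.015,
          "every": 48
        }
      }
    },
    {
      "id": "ecl_acute",
      "duration": 24,
      "efficacy": 0.0980185537261462,
      "successor": "ecl_recovery",
      "nurse_count": 1,
      "nurse_every": 1,
      "nurse_hold": true,
      "doctor_count": 1,
      "doctor_every": 8,
      "doctor_hold": false,
      "drugs": {
        "hydralazine": {
          "dose": 0.03,
          "every": 8
        }
      }
    },
    {
      "id": "ecl_recovery",
      "duration": 168,
      "efficacy": 0.0980185537261462,
      "successor": null,
      "nurse_count": 1,
      "nurse_every": 16,
      "nurse_hold": false,
      "doctor_count": 1,
      "doctor_every": 48,
      "doctor_hold": false,
      "drugs": {
        "hydralazine": {
          "dose": 0.015,
          "every": 56
        }
      }
    },
    {
      "id": "rup_surgical",
      "duration": 12,
      "efficacy": 0.102312867552686,
      "successor": "rup_recovery",
      "nurse_count": 2,
      "nurse_every": 1,
      "nurse_hold": true,
      "doctor_count": 2,
      "doctor_every": 1,
      "doctor_hold": true,
      "drugs": {
        "oxytocin": {
          "dose": 0.2,
          "every": 12
        }
      }
    },
    {
      "id": "rup_recovery",
      "duration": 180,
      "efficacy": 0.102312867552686,
      "successor": null,
      "nurse_count": 1,
      "nurse_every": 16,
      "nurse_hold": false,
      "doctor_count": 1,
      "doctor_every": 48,
      "doctor_hold": false,
      "drugs": []
    },
    {
      "id": "sep_acute",
      "duration": 16,
      "efficacy": 0.100643700414542,
      "successor": "sep_recovery",
      "nurse_count": 1,
      "nurse_every": 4,
      "nurse_hold": false,
      "doctor_count": 1,
      "doctor_every": 8,
      "doctor_hold": false,
      "drugs": []
    },
    {
      "id": "sep_recovery",
      "duration": 176,
      "efficacy": 0.100643700414542,
      "successor": null,
      "nurse_count": 1,
      "nurse_every": 24,
      "nurse_hold": false,
      "doctor_count": 1,
      "doctor_every": 48,
      "doctor_hold": false,
      "drugs": []
    }
  ],
  "inventory": {
    "stocks": {
      "oxytocin": 200,
      "hydralazine": 11
    },
    "restock_interval_cycles": 2880,
    "restock_amounts": {
      "oxytocin": 200,
      "hydralazine": 11
    },
    "restock_enabled": true,
    "units": {
      "oxytocin": "pack = 100 IU",
      "hydralazine": "pack = 200 mg/mL"
    }
  }
}
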