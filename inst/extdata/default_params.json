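{
  "meta": {
    "name": "fixture"
  },
  "risk_equations": {
    "hypertension_5yr": {
      "intercept": -12.07,
      "coefficients": {
        "LogBMI": 2.497,
        "CurrentSmoker": 0.775,
        "CurrentlyPrehypertensive": 1.71,
        "FamilyHistory": 0.656,
        "WorkFullTime": -0.059,
        "WorkPartTime": -0.135,
        "JobDemand": 0.167,
        "JobControl": -0.347,
        "Support": -0.16,
        "Age": 0.024,
        "Women": 0.197
      }
    },
    "prehypertension_5yr": {
      "intercept": -5.106,
      "coefficients": {
        "LogBMI": 0.013,
        "CurrentSmoker": -0.424,
        "CurrentlyPrehypertensive": 1.155,
        "FamilyHistory": 0.509,
        "WorkFullTime": 0.361,
        "WorkPartTime": 1.47,
        "JobDemand": -0.278,
        "JobControl": -0.657,
        "Support": -0.206,
        "Age": -0.078,
        "Women": 0.004
      }
    }
  },
  "transitions": {
    "use_risk_equations": true,
    "crude": {
      "normo_to_prehyp": 0.045,
      "normo_to_hyper": 0.008,
      "prehyp_to_hyper": 0.035
    },
    "prehyp_to_controlled": 0.032,
    "control_by_adherence": {
      "high": 0.3,
      "medium": 0.18,
      "low": 0.08
    },
    "prescription": {
      "white": 0.34,
      "Black": 0.4
    },
    "adherence_init": {
      "high": 0.52,
      "medium": 0.26,
      "low": 0.22
    }
  },
  "mortality": {
    "age_breaks": [25, 35, 45, 55],
    "cvd": {
      "white_male": [8e-05, 0.0003, 0.0011, 0.003],
      "Black_male": [0.000144, 0.00054, 0.00198, 0.0054],
      "white_female": [3e-05, 0.00012, 0.00045, 0.0013],
      "Black_female": [5.4e-05, 0.000216, 0.00081, 0.00234]
    },
    "non_cvd": {
      "white_male": [0.0013, 0.0025, 0.005, 0.0095],
      "Black_male": [0.001885, 0.003625, 0.00725, 0.013775],
      "white_female": [0.0007, 0.0014, 0.003, 0.006],
      "Black_female": [0.001015, 0.00203, 0.00435, 0.0087]
    },
    "pregnancy": {
      "white": [2e-05, 1e-05, 0, 0],
      "Black": [5e-05, 2.5e-05, 0, 0]
    },
    "hr_cvd_hypertensive": {
      "male": 1.6,
      "female": 2
    }
  },
  "behavior": {
    "smoking": {
      "age_breaks": [18, 30, 45],
      "never_to_current": [0.015, 0.004, 0.001],
      "current_to_former": [0.035, 0.045, 0.06],
      "former_to_current": [0.06, 0.03, 0.012]
    },
    "activity": {
      "inactive_to_active": 0.09,
      "active_to_inactive": 0.11
    },
    "bmi_drift": {
      "active": 0.1,
      "inactive": 0.25,
      "sd": 0.1,
      "floor": 12
    }
  },
  "employment": {
    "frozen": false,
    "intercept_unemployed": {
      "health_diagnosing": -4.45,
      "health_treating": -4.15,
      "technician": -3.25,
      "aide": -2.95
    },
    "intercept_part_time": {
      "health_diagnosing": -1.9,
      "health_treating": -1.3,
      "technician": -1.45,
      "aide": -1.1
    },
    "slopes_unemployed": {
      "age": 0,
      "female": 0.1,
      "Black": 0.25,
      "ever_unemployed": 0.9
    },
    "slopes_part_time": {
      "age": 0,
      "female": 0.6,
      "Black": 0.05,
      "ever_unemployed": 0.25
    }
  },
  "baselines": {
    "female_share": {
      "white": 0.813,
      "Black": 0.846
    },
    "family_history": {
      "white": 0.44,
      "Black": 0.58
    },
    "smoking": {
      "white_male": {
        "current": 0.26,
        "former": 0.08,
        "never": 0.66
      },
      "Black_male": {
        "current": 0.19,
        "former": 0.05,
        "never": 0.76
      },
      "white_female": {
        "current": 0.21,
        "former": 0.08,
        "never": 0.71
      },
      "Black_female": {
        "current": 0.12,
        "former": 0.04,
        "never": 0.84
      }
    },
    "log_bmi": {
      "white_male": {
        "meanlog": 3.266,
        "sdlog": 0.17
      },
      "Black_male": {
        "meanlog": 3.296,
        "sdlog": 0.17
      },
      "white_female": {
        "meanlog": 3.238,
        "sdlog": 0.2
      },
      "Black_female": {
        "meanlog": 3.367,
        "sdlog": 0.2
      }
    },
    "active": {
      "white_male": 0.56,
      "Black_male": 0.5,
      "white_female": 0.5,
      "Black_female": 0.38
    },
    "bp_state": {
      "white_male": {
        "normotensive": 0.6,
        "prehypertensive": 0.36,
        "hypertensive": 0.04
      },
      "Black_male": {
        "normotensive": 0.55,
        "prehypertensive": 0.39,
        "hypertensive": 0.06
      },
      "white_female": {
        "normotensive": 0.76,
        "prehypertensive": 0.21,
        "hypertensive": 0.03
      },
      "Black_female": {
        "normotensive": 0.68,
        "prehypertensive": 0.27,
        "hypertensive": 0.05
      }
    }
  },
  "pwe": {
    "demand": {
      "mean": {
        "health_diagnosing": 0.55,
        "health_treating": 0.4,
        "technician": 0.25,
        "aide": 0.5
      },
      "sd": {
        "health_diagnosing": 0.8,
        "health_treating": 0.8,
        "technician": 0.8,
        "aide": 0.8
      }
    },
    "control": {
      "mean": {
        "health_diagnosing": 1,
        "health_treating": 0.4,
        "technician": -0.2,
        "aide": -0.8
      },
      "sd": {
        "health_diagnosing": 0.8,
        "health_treating": 0.8,
        "technician": 0.8,
        "aide": 0.8
      }
    },
    "support": {
      "mean": {
        "health_diagnosing": 0.6,
        "health_treating": 0.3,
        "technician": 0,
        "aide": -0.4
      },
      "sd": {
        "health_diagnosing": 0.8,
        "health_treating": 0.8,
        "technician": 0.8,
        "aide": 0.8
      }
    }
  },
  "allocation": {
    "white_male": {
      "health_diagnosing": 0.312,
      "health_treating": 0.235,
      "technician": 0.291,
      "aide": 0.162
    },
    "Black_male": {
      "health_diagnosing": 0.109,
      "health_treating": 0.151,
      "technician": 0.33,
      "aide": 0.409
    },
    "white_female": {
      "health_diagnosing": 0.055,
      "health_treating": 0.409,
      "technician": 0.252,
      "aide": 0.283
    },
    "Black_female": {
      "health_diagnosing": 0.015,
      "health_treating": 0.205,
      "technician": 0.223,
      "aide": 0.557
    }
  },
  "composition": {
    "female_share_overall": 0.82,
    "white_share_men": 0.813,
    "white_share_women": 0.775
  },
  "provenance": {
    "risk_equation_hypertension": "CARDIA-estimated logistic risk equation (printed coefficients)",
    "risk_equation_prehypertension": "CARDIA-estimated logistic risk equation (printed coefficients)",
    "crude_transitions": "CARDIA year-15 crude transition probabilities; fixture values",
    "prehyp_to_controlled": "Appel 2003 behavioral modification; fixture value",
    "control_by_adherence": "Bramley 2006; fixture values",
    "prescription": "Samanic 2020; fixture values",
    "adherence_init": "Bramley 2006; fixture values",
    "mortality_cvd": "National Vital Statistics System 2017; fixture values",
    "mortality_non_cvd": "National Vital Statistics System 2017; fixture values",
    "mortality_pregnancy": "National Vital Statistics System 2017; fixture values",
    "cvd_hazard_ratio": "Franco 2005; fixture values",
    "smoking_transitions": "Yi 2017; fixture values",
    "activity_transitions": "Dalziel 2006; fixture values",
    "bmi_drift": "fixture",
    "family_history": "Muntner 2010; fixture values",
    "female_share": "ACS 2012-2017; fixture values",
    "smoking_baseline": "NHIS 2000-2018; fixture values",
    "bmi_baseline": "NHIS 2000-2018; fixture values",
    "bp_state_baseline": "NHANES 1999-2018; fixture values",
    "activity_baseline": "NHIS 2000-2018; fixture values",
    "employment_model": "ACS 2012-2017 gradient calibration (1%/1%/3%/4%); fixture coefficients",
    "pwe_distributions": "ACS 2012-2018 linked with O*NET 3.1; fixture standardized scale",
    "allocation_status_quo": "ACS 2012-2017 multinomial predictions (printed rows)",
    "composition_weights": "fixture-calibrated mixture weights"
  }
}
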