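{
  "generator": {
    "n_subjects": 8000,
    "prevalence_intercept": -3.4,
    "theta1_prime": 0.45,
    "theta2": -0.844,
    "beta1": -0.45,
    "covariate_effects": {
      "education": {
        "mediator": 0.1,
        "outcome": -0.25
      },
      "income_low": {
        "mediator": -0.1,
        "outcome": 0.3
      },
      "ets_exposure": {
        "mediator": -0.12,
        "outcome": 0.3
      },
      "maternal_age": {
        "mediator": 0.05,
        "outcome": -0.05
      },
      "gestational_age": {
        "mediator": 0.08,
        "outcome": -0.1
      },
      "sex_girl": {
        "mediator": 0,
        "outcome": 0
      }
    },
    "cpg_means": {
      "CpG_2": 0.36,
      "CpG_3.4": 0.365,
      "CpG_5": 0.48,
      "CpG_7": 0.185,
      "CpG_11": 0.37
    },
    "cpg_sds": {
      "CpG_2": 0.21,
      "CpG_3.4": 0.08,
      "CpG_5": 0.13,
      "CpG_7": 0.12,
      "CpG_11": 0.1
    },
    "cpg_blocks": {
      "block1": ["CpG_2", "CpG_3.4"],
      "block2": ["CpG_5", "CpG_7", "CpG_11"]
    },
    "cpg_block_corr": {
      "within": [0.66, 0.44],
      "between": 0.15
    },
    "mediator_residual_sd": 0.883562108739391,
    "girl_fraction": 0.588,
    "causal_cpg": "CpG_11",
    "girls_only_effect": true,
    "area_mean": 275,
    "area_sd": 55,
    "aspect_ratio_mean": 1.08,
    "aspect_ratio_sd": 0.04,
    "design": "case_control",
    "n_cases": 250,
    "n_controls": 250,
    "seed": 1
  },
  "assay": {
    "batch_size": 24,
    "repeat_per_batch": 1,
    "conversion_efficiency_range": [0.985, 0.999],
    "missing_rate": 0.03,
    "measurement_noise_sd": 0.01,
    "censor_low_rate": 0.01,
    "censor_high_rate": 0.005,
    "seed": 100
  },
  "thresholds": {
    "beta_lower": 0.05,
    "beta_upper": 0.95,
    "min_valid_fraction": 0.75,
    "repeat_max_diff": 0.05,
    "min_conversion": 0.98
  },
  "fragment_map": {
    "CpG_3.4": ["CpG_3", "CpG_4"]
  },
  "covariates": ["maternal_age", "education", "income_low", "ets_exposure", "gestational_age", "sex"],
  "drop_ets": false,
  "exclude_alcohol": false,
  "strata": ["all", "girls", "boys"],
  "alpha": 0.05,
  "mediation_alpha": 0.05,
  "bootstrap_reps": 50,
  "seed": 11
}
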