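{
  "meta": {
    "label": "Packaged base-case configuration: COPD early-warning system vs usual care",
    "price_year": 2021,
    "currency": "GBP",
    "notes": [
      "All probabilities are monthly unless suffixed _annual.",
      "death_on_admission is a placeholder: the source table is not in the public domain.",
      "usual_care transition matrix is back-derived from the intervention year-2 matrix by dividing beneficial cells by the year-2 relative risk and renormalising; it is a placeholder, not ground truth.",
      "year1 accruals double the 6-month imputed trial values; treat with the corresponding caveat."
    ]
  },
  "discount_rate_annual": 0.035,
  "horizon_months": 60,
  "wtp_grid": [0, 2500, 5000, 7500, 10000, 12500, 15000, 17500, 20000, 22500, 25000, 27500, 30000, 35000, 40000, 45000, 50000],
  "population_eligible": 626129,
  "death_on_admission": {
    "point": 0.05,
    "family": "beta",
    "alpha": 5,
    "beta": 95,
    "placeholder": true
  },
  "starting_states": {
    "pseudo_alpha": 0.05,
    "usual_care": {
      "A": {"alpha": 0.05, "beta": 23},
      "B": {"alpha": 3, "beta": 20.05},
      "C": {"alpha": 0.05, "beta": 23},
      "D": {"alpha": 20, "beta": 3.05}
    },
    "intervention": {
      "A": {"alpha": 0.05, "beta": 17},
      "B": {"alpha": 3, "beta": 14.05},
      "C": {"alpha": 1, "beta": 16.05},
      "D": {"alpha": 13, "beta": 4.05}
    }
  },
  "transitions": {
    "intervention_year2": {
      "A": {"B": {"point": 0.008, "alpha": 2, "beta": 282},
            "C": {"point": 0.011, "alpha": 3, "beta": 281},
            "D": {"point": 0.003, "alpha": 1, "beta": 283}},
      "B": {"A": {"point": 0.013, "alpha": 3, "beta": 225},
            "C": {"point": 0.002, "alpha": 1, "beta": 227},
            "D": {"point": 0.018, "alpha": 4, "beta": 224}},
      "C": {"A": {"point": 0.030, "alpha": 3, "beta": 93},
            "B": {"point": 0.054, "alpha": 0.5, "beta": 95.5},
            "D": {"point": 0.006, "alpha": 0.5, "beta": 95.5}},
      "D": {"A": {"point": 0.003, "alpha": 1, "beta": 253},
            "B": {"point": 0.015, "alpha": 4, "beta": 251},
            "C": {"point": 0.004, "alpha": 1, "beta": 253}}
    },
    "beneficial_cells": [["A", "B"], ["A", "D"], ["C", "B"], ["C", "D"]]
  },
  "exacerbations": {
    "rates": {
      "A": {"point": 0.0024, "alpha": 4.99, "beta": 20743.01},
      "B": {"point": 0.0078, "alpha": 5.88, "beta": 12839.12},
      "C": {"point": 0.0051, "alpha": 8.82, "beta": 3466.174},
      "D": {"point": 0.0157, "alpha": 5.57, "beta": 5057.422}
    },
    "effect_stages": ["B", "D"],
    "reduction_schedule": [0.12, 0.06, 0.03, 0.015]
  },
  "treatment_effect": {
    "base_rr_year2": {"point": 0.91, "family": "lognormal", "se": 0.604},
    "decay": 0.5,
    "bed_day_reduction": {"point": 1.278, "family": "normal", "se": 0.914}
  },
  "stage_params": {
    "utilities": {
      "A": {"point": 0.83, "family": "beta", "alpha": 65.56, "beta": 13.05},
      "B": {"point": 0.64, "family": "beta", "alpha": 145.37, "beta": 83.56},
      "C": {"point": 0.82, "family": "beta", "alpha": 70.86, "beta": 15.47},
      "D": {"point": 0.59, "family": "beta", "alpha": 164.33, "beta": 115.29}
    },
    "exac_disutility": {"point": 0.06, "family": "beta", "alpha": 376.50, "beta": 6048.44},
    "exac_disutility_per_month": true,
    "monthly_costs": {
      "B": {"point": 48.51, "family": "gamma", "shape": 4.75, "scale": 10.29},
      "D": {"point": 75.35, "family": "gamma", "shape": 16.43, "scale": 4.57},
      "ac_decrement": {"point": 33.10, "family": "gamma", "shape": 0.47, "scale": 70.80}
    },
    "admission_cost": {"point": 2258.33, "family": "normal", "se": 313.26},
    "bed_day_cost": {"point": 260.71, "family": "normal", "se": 44.12},
    "intervention_monthly_cost": {"point": 39.90, "family": "gamma", "shape": 3.98, "scale": 10.03}
  },
  "year1": {
    "usual_care": {
      "cost": {"point": 1713.38, "family": "gamma", "se": 401.26},
      "qaly": {"point": 0.476, "family": "normal", "se": 0.036}
    },
    "intervention": {
      "cost": {"point": 2119.38, "family": "gamma", "se": 310.16},
      "qaly": {"point": 0.548, "family": "normal", "se": 0.032}
    }
  },
  "intervention_costing": {
    "items": {
      "licence_fee": {"unit_cost": 120.00, "weight": 1, "recurrence": "annual"},
      "tablet": {"unit_cost": 100.00, "weight": 0.15, "recurrence": "annual"},
      "prescription_setup": {
        "hospital_cost": 31.00, "community_cost": 53.60, "hospital_share": 0.70,
        "printed_cost": 37.96, "recurrence": "first_year_only"
      },
      "clinical_support": {"unit_cost": 65.78, "weight": 1, "recurrence": "annual"},
      "crp_analyser": {"unit_cost": 1.60, "weight": 1, "recurrence": "first_year_only"},
      "crp_cartridges": {"unit_cost": 30.00, "weight": 1, "recurrence": "annual"},
      "spirometer": {"unit_cost": 90.00, "weight": 1, "recurrence": "first_year_only"},
      "training": {"unit_cost": 2.24, "weight": 1, "recurrence": "first_year_only"}
    },
    "printed_subtotals": {
      "app_first_year": 238.73,
      "app_subsequent_year": 200.78,
      "crp_first_year": 31.60,
      "crp_subsequent_year": 30.00
    },
    "printed_totals": {
      "first_year": 362.57,
      "subsequent_year": 231.23
    }
  },
  "trial_summaries": {
    "eq5d_means": {
      "months": [0, 3, 6],
      "intervention": [0.529, 0.537, 0.587],
      "usual_care": [0.487, 0.463, 0.490]
    },
    "nhs_cost_components": {
      "labels": ["intervention", "home_visits", "primary_care", "ae_attendance",
                 "pharmaceuticals", "niv_rehab", "hospitalisation"],
      "intervention": [181.29, 125.43, 73.41, 34.37, 212.53, 170.40, 262.26],
      "usual_care": [0, 0, 51.16, 34.93, 256.33, 133.89, 380.38],
      "printed_totals": {"intervention": 1059.69, "usual_care": 856.69, "difference": 203.00}
    },
    "hospitalisations_6m": {"intervention": 0.128, "usual_care": 0.146}
  }
}
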