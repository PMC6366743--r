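{
  "cambridge": {
    "label": "Cambridge Diabetes Risk model",
    "intercept": -6.322,
    "terms": [
      {"name": "female", "label": "Female gender", "coefficient": -0.879,
       "derivation": {"type": "sex", "level": "female"}},
      {"name": "antihypertensive", "label": "Use of antihypertensive medication", "coefficient": 1.222,
       "derivation": {"type": "flag", "field": "antihypertensive"}},
      {"name": "corticosteroids", "label": "Prescribed steroids", "coefficient": 2.191,
       "derivation": {"type": "flag", "field": "corticosteroids"}},
      {"name": "age", "label": "Age (years)", "coefficient": 0.063,
       "derivation": {"type": "continuous", "field": "age"}},
      {"name": "bmi_25_27", "label": "25 <= BMI < 27.5 kg/m2", "coefficient": 0.699,
       "derivation": {"type": "range", "field": "bmi", "min": 25, "max": 27.5}, "band": "bmi"},
      {"name": "bmi_27_30", "label": "27.5 <= BMI < 30 kg/m2", "coefficient": 1.970,
       "derivation": {"type": "range", "field": "bmi", "min": 27.5, "max": 30}, "band": "bmi"},
      {"name": "bmi_30", "label": "BMI >= 30 kg/m2", "coefficient": 2.518,
       "derivation": {"type": "range", "field": "bmi", "min": 30}, "band": "bmi"},
      {"name": "fh_parent_or_sibling", "label": "Parent or sibling has diabetes", "coefficient": 0.728,
       "derivation": {"type": "family_history", "rule": "parent_or_sibling"}},
      {"name": "fh_parent_and_sibling", "label": "Parent and sibling has diabetes", "coefficient": 0.753,
       "derivation": {"type": "family_history", "rule": "parent_and_sibling"}},
      {"name": "smoking_ex", "label": "Ex-smoker", "coefficient": -0.218,
       "derivation": {"type": "level", "field": "smoking", "level": "ex"}, "band": "smoking"},
      {"name": "smoking_current", "label": "Current smoker", "coefficient": 0.855,
       "derivation": {"type": "level", "field": "smoking", "level": "current"}, "band": "smoking"}
    ]
  },
  "kuwaiti": {
    "label": "Kuwaiti Risk model",
    "intercept": -5.018,
    "terms": [
      {"name": "fh_sibling", "label": "Sibling history of diabetes", "coefficient": 0.979,
       "derivation": {"type": "family_history", "rule": "sibling"}},
      {"name": "antihypertensive", "label": "Use of antihypertensive medication", "coefficient": 0.978,
       "derivation": {"type": "flag", "field": "antihypertensive"}},
      {"name": "age_35", "label": "Age >= 35 years", "coefficient": 1.315,
       "derivation": {"type": "range", "field": "age", "min": 35}},
      {"name": "wc_gt100", "label": "Waist circumference > 100 cm", "coefficient": 1.930,
       "derivation": {"type": "range", "field": "waist", "min": 100, "min_open": true}}
    ]
  },
  "omani": {
    "label": "Omani Diabetes Risk model",
    "intercept": -4.700,
    "terms": [
      {"name": "age_40_59", "label": "40 <= age <= 59 years", "coefficient": 1.800,
       "derivation": {"type": "range", "field": "age", "min": 40, "max": 60}, "band": "age"},
      {"name": "age_60", "label": "Age >= 60 years", "coefficient": 2.300,
       "derivation": {"type": "range", "field": "age", "min": 60}, "band": "age"},
      {"name": "wc_sex_high", "label": "WC >= 94 cm (M) / >= 80 cm (W)", "coefficient": 0.380,
       "derivation": {"type": "waist_sex_cutoff", "male": 94, "female": 80}},
      {"name": "bmi_25_30", "label": "25 <= BMI < 30 kg/m2", "coefficient": 0.540,
       "derivation": {"type": "range", "field": "bmi", "min": 25, "max": 30}, "band": "bmi"},
      {"name": "bmi_30", "label": "BMI >= 30 kg/m2", "coefficient": 0.690,
       "derivation": {"type": "range", "field": "bmi", "min": 30}, "band": "bmi"},
      {"name": "fh_parent_or_sibling", "label": "Parental or sibling history of diabetes", "coefficient": 1.900,
       "derivation": {"type": "family_history", "rule": "parent_or_sibling"}},
      {"name": "bp_high", "label": "SBP >= 140 and/or DBP >= 90 mmHg", "coefficient": 0.730,
       "derivation": {"type": "bp_either", "sbp": 140, "dbp": 90}}
    ]
  },
  "rotterdam": {
    "label": "Rotterdam Predictive model",
    "intercept": -3.020,
    "terms": [
      {"name": "age5_over55", "label": "Age per 5 years: 55 years to >75", "coefficient": 0.190,
       "derivation": {"type": "age_increments", "field": "age", "start": 55, "step": 5, "cap": 5}},
      {"name": "male", "label": "Male gender", "coefficient": 0.460,
       "derivation": {"type": "sex", "level": "male"}},
      {"name": "antihypertensive", "label": "Use of antihypertensive medication", "coefficient": 0.420,
       "derivation": {"type": "flag", "field": "antihypertensive"}},
      {"name": "bmi_30", "label": "BMI >= 30 kg/m2", "coefficient": 0.510,
       "derivation": {"type": "range", "field": "bmi", "min": 30}}
    ]
  },
  "finnish": {
    "label": "Simplified Finnish Diabetes Risk model",
    "intercept": -5.514,
    "terms": [
      {"name": "age_45_54", "label": "45 <= age <= 54 years", "coefficient": 0.628,
       "derivation": {"type": "range", "field": "age", "min": 45, "max": 55}, "band": "age"},
      {"name": "age_55_64", "label": "55 <= age <= 64 years", "coefficient": 0.892,
       "derivation": {"type": "range", "field": "age", "min": 55, "max": 65}, "band": "age"},
      {"name": "bmi_25_30", "label": "25 <= BMI < 30 kg/m2", "coefficient": 0.165,
       "derivation": {"type": "range", "field": "bmi", "min": 25, "max": 30}, "band": "bmi"},
      {"name": "bmi_30", "label": "BMI >= 30 kg/m2", "coefficient": 1.096,
       "derivation": {"type": "range", "field": "bmi", "min": 30}, "band": "bmi"},
      {"name": "wc_band_mid", "label": "94 <= WC < 102 cm (M) / 80 <= WC < 88 cm (W)", "coefficient": 0.857,
       "derivation": {"type": "waist_sex_range", "male_min": 94, "male_max": 102, "female_min": 80, "female_max": 88}, "band": "wc"},
      {"name": "wc_band_high", "label": "WC >= 102 cm (M) / >= 88 cm (W)", "coefficient": 1.350,
       "derivation": {"type": "waist_sex_cutoff", "male": 102, "female": 88}, "band": "wc"},
      {"name": "antihypertensive", "label": "Use of antihypertensive medication", "coefficient": 0.711,
       "derivation": {"type": "flag", "field": "antihypertensive"}}
    ],
    "fixed_zero_terms": ["high_glucose_history"]
  }
}
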