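{
  "factors": [
    {"factor_id": "pain_symptoms", "name": "Pain severity and clinical symptoms", "weight": 0.22},
    {"factor_id": "stress_test", "name": "Stress test result", "weight": 0.18},
    {"factor_id": "underlying_disease", "name": "Underlying diseases and risk factors", "weight": 0.15},
    {"factor_id": "mi_count", "name": "Number of myocardial infarctions (heart failure rate)", "weight": 0.15},
    {"factor_id": "socioeconomic_performance", "name": "Decreased economic and social performance", "weight": 0.12},
    {"factor_id": "waiting_time", "name": "Duration of waiting time", "weight": 0.10},
    {"factor_id": "special_circumstances", "name": "Special circumstances", "weight": 0.08}
  ],
  "score_min": 0,
  "score_max": 10,
  "scale": 10,
  "tiers": [
    {"tier": 1, "min_points": 80, "max_wait_weeks": 4},
    {"tier": 2, "min_points": 50, "max_wait_weeks": 8},
    {"tier": 3, "min_points": 0, "max_wait_weeks": 16}
  ]
}
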