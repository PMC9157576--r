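# Published model parameters: costs already converted to USD (exchange rate
# 7.012 CNY/USD is metadata only and is never applied by the engine).
wtp: 29307
cycle:
  cycle_length_days: 42
  horizon_cycles: 43
  annual_discount_rate: 0.03
dsa:
  cost: 0.50
  utility: 0.30
  transition: 0.30
psa:
  n_iterations: 1000
currency:
  unit: USD
  exchange_rate_cny_per_usd: 7.012
arms:
  - name: sHPN
    role: intervention
    survival:
      shape: 0.89735193
      scale: 0.05464799
      time_unit_days: 42
    # baseline, visit 2, visit 3, visit 4, visit 5
    utilities: [0.60, 0.67, 0.69, 0.78, 0.69]
    costs:
      - {name: PN,             amount: 421.58, recurrence: per_cycle}
      - {name: CVC,            amount: 64.48,  recurrence: once}
      - {name: CVC care,       amount: 221.79, recurrence: per_cycle}
      - {name: PICC,           amount: 359.38, recurrence: once}
      - {name: Homecare nurse, amount: 41.07,  recurrence: per_cycle}
      - {name: Ward,           amount: 8.56,   recurrence: once}
      - {name: Readmission,    amount: 365.70, recurrence: once}
      - {name: Supportive care, amount: 675.00, recurrence: per_cycle}
      - {name: Follow-up,      amount: 111.20, recurrence: per_cycle}
  - name: Non-sHPN
    role: comparator
    survival:
      shape: 0.95341849
      scale: 0.04435547
      time_unit_days: 42
    utilities: [0.64, 0.65, 0.53, 0.60, 0.56]
    costs:
      - {name: Readmission,    amount: 365.70, recurrence: once}
      - {name: EN,             amount: 3.54,   recurrence: once}
      - {name: Supportive care, amount: 675.00, recurrence: per_cycle}
      - {name: Follow-up,      amount: 111.20, recurrence: per_cycle}
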