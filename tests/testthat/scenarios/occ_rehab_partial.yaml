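# Employer not ready, but occupational rehabilitation bridges the shortfall:
# partial RTW with a $10,000 charge to the system ledger.
worker:
  health: 80
  responsiveness: 0.1
  stage: treatment
levers:
  rtw_policy: encourage
  early_rtw_health_floor: 70
  occ_rehab_enabled: true
  occ_rehab_capacity: 1
n_steps: 1
draws: [0.99, 0.5, 0.5, 0.1]
expected_transitions:
  - {from: general_population, to: treatment, tag: injected}
  - {from: treatment, to: rtw_pool, tag: partial_rtw_occ_rehab}
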