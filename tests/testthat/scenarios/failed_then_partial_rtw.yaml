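# Encouraged early RTW: the first employer attempt fails (readiness 3 below
# the 15-point shortfall), the second succeeds -> partial RTW; at work the
# worker drifts but stays below threshold.
worker:
  health: 80
  responsiveness: 0.1
  stage: treatment
levers:
  rtw_policy: encourage
  early_rtw_health_floor: 70
n_steps: 3
draws: [0.99, 0.5, 0.5, 0.1, 0.99, 0.5, 0.5, 0.9, 0.5]
expected_transitions:
  - {from: general_population, to: treatment, tag: injected}
  - {from: treatment, to: treatment, tag: failed_rtw}
  - {from: treatment, to: rtw_pool, tag: partial_rtw}
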