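# GP referral -> claim lodged (step 1), adjudicated and accepted -> treated
# -> full RTW (step 2). Draw order: gp correctness, gp cost | adjudication,
# treatment denial, treatment noise (0.5 -> zero), treatment cost.
worker:
  health: 94.9
  responsiveness: 1.0
  injury_type: acute_physical
  stage: gp
n_steps: 2
draws: [0.05, 0.5, 0.05, 0.99, 0.5, 0.5]
expected_transitions:
  - {from: general_population, to: gp, tag: injected}
  - {from: gp, to: claim_lodgement, tag: gp_referral}
  - {from: claim_lodgement, to: claim_accepted_waiting, tag: claim_accepted}
  - {from: claim_accepted_waiting, to: treatment, tag: admitted}
  - {from: treatment, to: rtw_pool, tag: full_rtw}
  - {from: rtw_pool, to: exited, tag: rtw_exit}
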