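# Emergency presentation below threshold -> straight to lodgement, accepted,
# treated.
worker:
  health: 40
  stage: emergency
  injury_type: acute_physical
n_steps: 2
draws: [0.05, 0.99, 0.5, 0.5]
expected_transitions:
  - {from: general_population, to: emergency, tag: injected}
  - {from: emergency, to: claim_lodgement, tag: ed_referral}
  - {from: claim_lodgement, to: claim_accepted_waiting, tag: claim_accepted}
  - {from: claim_accepted_waiting, to: treatment, tag: admitted}
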