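# Claim denied -> dispute -> lost -> worker leaves the scheme.
worker:
  health: 40
  fight_appetite: 100
  trust: 0
  injury_type: acute_physical
  stage: gp
levers:
  dispute_duration: 1
n_steps: 3
draws: [0.05, 0.5, 0.95, 0.5, 0.9]
expected_transitions:
  - {from: general_population, to: gp, tag: injected}
  - {from: gp, to: claim_lodgement, tag: gp_referral}
  - {from: claim_lodgement, to: dispute, tag: claim_denied}
  - {from: dispute, to: exited, tag: dispute_lost}
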