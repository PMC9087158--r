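# GP misdiagnoses an unfit worker back to the workplace; the workplace check
# returns them to lodgement (with a trust penalty); the claim is denied and
# the fully trusting, zero-fight worker gives up and leaves.
worker:
  health: 40
  trust: 100
  fight_appetite: 0
  stage: gp
  injury_type: acute_physical
n_steps: 2
draws: [0.95, 0.5, 0.5, 0.95, 0.5]
expected_transitions:
  - {from: general_population, to: gp, tag: injected}
  - {from: gp, to: workplace_check, tag: gp_referral}
  - {from: workplace_check, to: claim_lodgement, tag: sent_back}
  - {from: claim_lodgement, to: exited, tag: claim_denied}
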