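# Claim denied -> worker disputes (fight 100, trust 0 forces it) -> dispute
# won -> re-lodged at the back of the queue -> accepted on retry.
worker:
  health: 40
  fight_appetite: 100
  trust: 0
  injury_type: acute_physical
  stage: gp
levers:
  dispute_duration: 1
n_steps: 4
draws: [0.05, 0.5, 0.95, 0.5, 0.05, 0.05, 0.99, 0.5, 0.5]
expected_transitions:
  - {from: general_population, to: gp, tag: injected}
  - {from: gp, to: claim_lodgement, tag: gp_referral}
  - {from: claim_lodgement, to: dispute, tag: claim_denied}
  - {from: dispute, to: claim_lodgement, tag: dispute_won}
  - {from: claim_lodgement, to: claim_accepted_waiting, tag: claim_accepted}
  - {from: claim_accepted_waiting, to: treatment, tag: admitted}
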