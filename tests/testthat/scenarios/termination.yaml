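# Non-responsive worker with an accepted claim: benefits terminate once the
# claim duration strictly surpasses the 2-step maximum.
worker:
  health: 20
  responsiveness: 0.0
  stage: claim_lodgement
  injury_type: acute_physical
levers:
  max_claim_duration: 2
n_steps: 4
draws: [0.05, 0.99, 0.5, 0.5, 0.99, 0.5, 0.5, 0.99, 0.5, 0.5, 0.99, 0.5, 0.5]
expected_transitions:
  - {from: general_population, to: claim_lodgement, tag: injected}
  - {from: claim_lodgement, to: claim_accepted_waiting, tag: claim_accepted}
  - {from: claim_accepted_waiting, to: treatment, tag: admitted}
  - {from: treatment, to: exited, tag: terminated}
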