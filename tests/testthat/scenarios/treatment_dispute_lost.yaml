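# Treatment denied -> dispute (forced by fight 100, trust 0) -> dispute lost
# -> re-entry through the claim-acceptance pathway and back into treatment.
worker:
  health: 50
  responsiveness: 0.8
  fight_appetite: 100
  trust: 0
  stage: treatment
levers:
  dispute_duration: 1
n_steps: 2
draws: [0.01, 0.5, 0.5, 0.9, 0.99, 0.5, 0.5]
expected_transitions:
  - {from: general_population, to: treatment, tag: injected}
  - {from: treatment, to: dispute, tag: treatment_denied}
  - {from: dispute, to: claim_accepted_waiting, tag: dispute_lost}
  - {from: claim_accepted_waiting, to: treatment, tag: admitted}
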