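# Emergency presentation above the claim threshold -> workplace check ->
# drift pushes health over the threshold -> leaves the scheme uninjured.
worker:
  health: 96
  stage: emergency
n_steps: 1
draws: [0.999]
expected_transitions:
  - {from: general_population, to: emergency, tag: injected}
  - {from: emergency, to: workplace_check, tag: ed_referral}
  - {from: workplace_check, to: exited, tag: recovered}
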