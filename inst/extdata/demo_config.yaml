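# Demo configuration for run_pipeline(): synthesizes all three arms at
# small sizes with a fixed seed, so two runs are byte-identical.
arm: all
seed: 17
pharmacovigilance:
  generator:
    n_reports: 5000
    exposure_odds_multiplier: 0.5
  haldane: true
vonfrey:
  generator:
    groups:
      vehicle: 10
      paclitaxel: 1.5
      paclitaxel_treated: 5
    n_sessions: 6
morphometry:
  generator:
    n_fibers: 30
    conditions:
      control: 0
      degenerated: 0.6
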