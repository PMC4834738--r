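# Example program configuration: every knob the program exposes, in
# one audited file.  Omitted keys fall back to package defaults.
band:
  type: percent_baseline
  value: 2
flags:
  trail_window: 7
  min_points: 3
  edge_frac: 0.2
  plateau_conf: 0.95
trigger_k: 3
trigger_n: 5
trigger_states: RED
episode_window: 14
reminder_after: 3
step_increment: 3000
tip_phases:
  - start_week: 1
    end_week: 8
    cadence: weekly
  - start_week: 9
    end_week: 16
    cadence: biweekly
  - start_week: 17
    end_week: 24
    cadence: monthly
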