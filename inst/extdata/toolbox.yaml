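# Example toolbox catalogue: least intense (rank 1) first.
- id: self_monitoring
  label: Adopt a food-intake self-monitoring plan
  intensity_rank: 1
  cost_tier: low
- id: increase_activity
  label: Increase daily activity or exercise
  intensity_rank: 2
  cost_tier: low
- id: portion_controlled_foods
  label: Use portion-controlled foods
  intensity_rank: 3
  cost_tier: medium
- id: increase_contact
  label: Increase contact frequency with clinician
  intensity_rank: 4
  cost_tier: high
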