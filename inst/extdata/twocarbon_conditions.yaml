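# Condition layout for the bundled two-carbon fixture: an abundant
# glucose-analog reference and two nutrient-limited perturbations at 20% of
# the reference growth rate.
reference:
  exchange: EX_GLC
  uptake: 10
growth_fraction: 0.2
conditions:
  - name: glucose_low
    exchange: EX_GLC
    mode: fixed_fraction
  - name: alt_carbon
    exchange: EX_ETH
    mode: fixed_fraction
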