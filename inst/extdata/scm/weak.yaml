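# Same graph as `strong` with modest effects and half-SD shifts:
# a low-power regime where empty estimates become common.
names: [X1, X2, X3, X4, X5, X6]
edges:
- {from: X3, to: X1, weight: 1.0}
- {from: X4, to: X2, weight: 1.0}
outcome_weights: {X1: 0.4, X2: -0.4}
outcome_intercept: 0.0
noise_scales: {X1: 1.0, X2: 1.0, X3: 1.0, X4: 1.0, X5: 1.0, X6: 1.0}
interventions:
  "1":
  - {var: X1, type: shift, magnitude: 0.5}
  - {var: X2, type: shift, magnitude: -0.5}
  - {var: X3, type: shift, magnitude: 0.5}
  - {var: X4, type: shift, magnitude: -0.5}
  - {var: X5, type: shift, magnitude: 0.5}
  - {var: X6, type: shift, magnitude: -0.5}
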