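# Well-separated ground truth: two parents (X1, X2) with non-parent
# ancestors (X3 -> X1, X4 -> X2). Environment 1 mean-shifts every
# predictor (never the outcome or its mechanism), so each parent's
# distribution changes and the parent set is identifiable: the invariant
# sets are exactly the supersets of {X1, X2}.
names: [X1, X2, X3, X4, X5, X6]
edges:
- {from: X3, to: X1, weight: 1.0}
- {from: X4, to: X2, weight: 1.0}
outcome_weights: {X1: 1.2, X2: -1.2}
outcome_intercept: 0.0
noise_scales: {X1: 1.0, X2: 1.0, X3: 1.0, X4: 1.0, X5: 1.0, X6: 1.0}
interventions:
  "1":
  - {var: X1, type: shift, magnitude: 1.0}
  - {var: X2, type: shift, magnitude: -1.0}
  - {var: X3, type: shift, magnitude: 1.0}
  - {var: X4, type: shift, magnitude: -1.0}
  - {var: X5, type: shift, magnitude: 1.0}
  - {var: X6, type: shift, magnitude: -1.0}
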