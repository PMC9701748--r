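# Planted-signal benchmark for the lasso screen: 18 independent
# predictors, strong coefficients on X1 and X2 only, no interventions.
names: [X1, X2, X3, X4, X5, X6, X7, X8, X9, X10, X11, X12, X13, X14, X15, X16, X17, X18]
edges: []
outcome_weights: {X1: 1.0, X2: -1.0}
outcome_intercept: 0.0
noise_scales: {X1: 1.0}
interventions: {}
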