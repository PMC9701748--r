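---
title: "Invariant causal prediction for rare binary outcomes: models, defaults and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Invariant causal prediction for rare binary outcomes: models, defaults and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icpbin)
```

## The estimation problem

Risk factors for a rare clinical event — the motivating case is suicidal
behavior over a one-year follow-up in a primary-care cohort, observed in
about 2% of patients — are almost all weakly correlated with the outcome,
and regression coefficients cannot separate direct causes from variables
that merely share confounders with the outcome. Invariant causal
prediction (ICP) attacks the problem with one structural assumption: the
conditional distribution of the outcome $Y$ given its *direct causes*
$X_{S^*}$ is the same in every environment, because environments act on
variables other than the outcome's own mechanism. Any set of predictors
whose conditional law is *not* stable across environments therefore cannot
be exactly the set of direct causes.

The estimator implemented here, for binary $Y$ and a two-level environment
indicator $E$:

1. for a candidate subset $S$, fit the pooled logistic regression
   $\mathrm{logit}\, P(Y = 1 \mid X_S) = \beta_0 + \beta^\top X_S$ over
   all rows;
2. form response residuals $r_i = y_i - \hat p_i$;
3. split the residuals by environment level and apply a Welch two-sample
   $t$-test of equal means;
4. **accept** $S$ when $p \ge \alpha$ (invariance not rejected);
5. estimate the causal set as
   $\hat S = \bigcap \{ S : S \text{ accepted} \}$.

Because $S^*$ itself is accepted with probability at least $1 - \alpha$,
the estimate satisfies the coverage guarantee
$P(\hat S \subseteq S^*) \ge 1 - \alpha$, which
`coverage_experiment()` verifies by simulation.

Two terminal states are distinguished. If accepted subsets exist but share
no predictor, the estimate is the empty set (`empty_by_intersection`,
rendered `None`); in particular, accepting the empty subset — no
detectable environment effect on the outcome's margin — forces this state.
If *no* subset is accepted (`model_rejected`, rendered `-`), the
invariance assumption itself failed for every candidate, which is a
different scientific statement. Published tables of this kind do not
define their dash convention; ours is a documented choice, not a claim
about what any particular authors meant.

### The acceptance direction

Step 4 follows the standard convention: a subset survives when the test
*fails to reject* invariance, so stricter $\alpha$ (smaller) accepts
*more* subsets and drives the intersection toward the empty set. One
verbal description of this procedure in the applied literature states the
reverse ("accept when $p < \alpha$"), but that reading contradicts both
the accompanying claim that subsets are more likely to be accepted as the
significance level drops and the empirical pattern of fewer findings at
stricter levels. We implement the standard convention and expose
`reverse_acceptance = TRUE` in `invariance_test()`, `test_subset()` and
`icp()` so the alternative reading can be run as a sensitivity analysis
rather than guessed at.

### Test choices

* **Residual type.** Response residuals $y - \hat p$ are the default;
  Pearson and deviance residuals are available through `residual_type`.
  The three can disagree on borderline subsets; no equivariance of the
  decision under residual-type switch is claimed.
* **Welch, two-sided, no continuity correction.** The unequal-variance
  form is the robust default; with a rare outcome the residual variance
  differs mechanically between environments whenever event rates do.
  Degenerate inputs are defined explicitly: identical zero-variance
  samples give $t = 0, p = 1$ (invariant by definition); zero-variance
  samples with different means give $p = 0$.
* **Separation.** With ~2% events, subsets can separate the outcome. A
  fit that fails to converge or touches boundary fitted values is refit
  with a ridge penalty of $10^{-6}$ on slopes only (never the intercept)
  and flagged `regularization_used = "tiny-ridge"`; fitted probabilities
  are clamped to the open interval. An untestable subset raises an error
  instead of being dropped, because silently dropping a subset biases the
  intersection.
* **Pooled fitting.** One fit over all environments, per the plain
  reading of the procedure; per-environment fitting is out of scope.
* **No multiplicity correction** across subsets, environments or
  $\alpha$ levels, matching how such grids are reported.

### Known calibration nuance

The $t$-test treats $\hat p$ as fixed, but the logistic parameters are
estimated from the pooled sample. When interventions shift the *parents*
themselves, the fitted model absorbs part of the between-environment
residual difference and the null $p$-values on $S^*$ become conservative
(stochastically larger than uniform); when interventions do not reach the
parents, they are uniform to the resolution of a Kolmogorov–Smirnov check
at the 1% level over 250 replicates (tested). Conservativeness inflates
coverage and never deflates it, so the guarantee is unaffected; power
against non-invariant subsets is what pays.

### Monotonicity in $\alpha$

Acceptance regions are nested — $p \ge 0.05$ implies $p \ge 0.01$ — so
the accepted-set collection grows as $\alpha$ shrinks and the estimates
are nested, $\hat S(0.01) \subseteq \hat S(0.05) \subseteq \hat S(0.1)$,
*except* across a model-rejection boundary: if every subset is rejected
at $\alpha = 0.1$ but some survive at $\alpha = 0.05$, the larger-level
estimate is the empty set by convention while the smaller-level one need
not be. The tests assert the conditional form on a low-power family
(where rejection happens) and the unconditional chain on the
well-separated family (where model rejection has negligible
probability).

## Subset search and the lasso screen

`enumerate_subsets()` yields all $2^p$ subsets in size-then-lexicographic
order, so every report is byte-reproducible; `max_size` caps the
enumeration (the full method over 18 predictors is $2^{18} = 262{,}144$
fits — permitted, but the shipped study runs cap the full method at pairs,
which is where this cohort's signal lives if anywhere). The `lasso`
method first reduces the pool by L1-penalized logistic regression with the
penalty chosen at the 10-fold cross-validated deviance minimum
(fold assignment seeded). CV-min rather than 1-SE is deliberate: the
screen must over-select rather than drop a true parent, because the
intersection tolerates extra candidates but is broken by missing ones.
Retained predictors are truncated to the `k_max = 8` largest absolute
coefficients — published invariant sets of this kind have at most three
members, and $2^8 = 256$ subsets keep the search trivial.

## The synthetic-data generators

Real data of the motivating kind are restricted, so the package ships two
generators that are first-class, tested code.

### Structural causal models (`scm_spec()`, `simulate_scm()`)

Linear-Gaussian predictors over an acyclic weight matrix, a logistic
outcome on its parents, and per-environment interventions (`shift`,
`scale`, `do`) that may target any predictor but never the outcome or its
mechanism — the invariance assumption holds by construction, which is
what makes these models the validation oracle. Draws are pure functions
of `(spec, n, seed)`.

A design point discovered during development and worth recording: if
interventions shift only variables that are *not* ancestors of the
outcome, no subset ever becomes non-invariant and the population estimate
is the empty set; and if shifts reach a parent $k$ only through a
non-parent ancestor $A$, then $(S^* \setminus \{k\}) \cup \{A\}$ is also
invariant ($A$ screens off $k$), so $k$ can never survive the
intersection. Parent-set identifiability requires the parents' own
distributions to change across environments. The shipped presets
(`scm_preset()`) therefore shift every predictor in environment 1 with
non-cancelling signs; `shift_nonparents()` remains available to construct
the non-parent-only regime, which is precisely the regime that produces
empty estimates. Preset magnitudes: `strong` (weights $\pm 1.2$, 1-SD
shifts) gives near-certain recovery of $\{X_1, X_2\}$ at
$n = 2000$ per environment; `weak` ($\pm 0.4$, 0.5-SD) is a realistic
low-power regime; `rare` adds a ~2% event rate; `planted` is the
18-predictor lasso benchmark.

### The cohort emulator (`default_schema()`, `generate_study_like()`)

The schema records, per instrument scale, the published mean, SD and
range (18 predictors: 17 scale totals plus age), six environment
prevalences taken from published counts over $n = 2744$, and a 2.1%
one-year event rate. Emulation choices, each made once:

* **Marginals: censored (clipped) normal with moment-matched underlying
  parameters.** Hard truncation at the instrument bounds cannot reach
  the published moments — a floor-heavy scale like internal entrapment
  (mean 5.8, SD 8.8 on 0–40) needs more mass at the bound than a
  truncated normal can carry, and a scale with SD greater than its mean
  (suicide cognitions: 6.6, SD 11.0) is shaped like "mostly zero plus a
  long tail". Clipping concentrates that mass at the bound, and the
  underlying $(\mu, \sigma)$ are calibrated per predictor by Nelder–Mead
  on closed-form censored-normal moments, so sample means converge to
  their targets (verified within $0.05 \cdot$SD at $n = 10^5$). The most
  skewed scales can undershoot the target SD slightly; means are exact.
  Values are continuous where real scale totals are integers — item-level
  psychometrics are out of scope.
* **Dependence: one latent distress factor.** Clinical scales share an
  exchangeable correlation (default `rho = 0.3`) through a single latent
  factor; published sources report no inter-scale correlation matrix, and
  inventing one would suggest precision we do not have. Age is drawn
  independently of the factor.
* **Environments.** History variables (prior ideation, attempt,
  non-suicidal self-injury) load positively on the same factor (0.45),
  race and gender weakly (−0.15, −0.10), so environments correlate with
  the outcome — a requirement for them to be informative — without being
  its descendants (they are confounded with it, not caused by it). The
  age environment thresholds the simulated age at $\le 23$; its
  prevalence is whatever the calibrated age marginal implies (~0.28 —
  higher than a real military-clinic cohort's young fraction, a direct
  consequence of the censored-normal family absorbing the 18-year floor).
* **Outcome.** Logistic on standardized predictors with small synthetic
  weights on shame (0.35), suicide cognitions (0.35), negative affect
  (0.25) and internal entrapment (0.15); the intercept is bisected so the
  mean fitted probability equals the target rate exactly. **These weights
  are placeholders** chosen to mirror the kind of variables that appear
  in published invariant sets; they are not estimates of any real cohort
  and must never be read as such.

What passing tests on these generators show — and what they do not: they
validate the estimator's statistical behavior (coverage, monotonicity,
power, screening) under a correctly specified logistic mechanism with
known ground truth. They do not certify behavior under model
misspecification, item-level measurement error, missing data (no
missingness mechanism is simulated), or informative follow-up, all of
which real cohorts have.

## Simulation experiments

`coverage_experiment()` draws replicate datasets, runs the estimator at
every requested $\alpha$ on shared per-subset $p$-values (so levels are
compared on identical draws), and reports empirical coverage
$P(\hat S \subseteq S^*)$, mean recovered parent fraction (1 by
convention when $S^* = \emptyset$), and the empty-estimate fraction,
with the full per-replicate seed list attached. Replicates default to
200, putting the Monte Carlo SE near 1.5% at the 0.95 level.
`rare_event_experiment()` recalibrates the intercept by bisection to a
target prevalence and reruns the experiment: comparing 50% against 2.1%
prevalence at $n = 1372$ per environment shows the power collapse that
makes predominantly empty estimates the expected outcome in a cohort of
this size — the indeterminacy pattern, reproduced end-to-end by
`run_study_analysis()` on an emulated cohort of 2744 (36-cell grid:
2 methods × 6 environments × 3 levels; the full method capped at
pair subsets, the lasso method screened to 8 of 18 predictors).

## Problem sizes used by the shipped checks

Schema fidelity at $n = 10^5$; Welch-oracle agreement on 1000 random
small samples at $10^{-10}$; coverage on the strong preset with 200
replicates of 2000 per environment; $\alpha$-monotonicity on 100
datasets of 1000 per environment; the study grid at the cohort's own
$n = 2744$; lasso retention over 100 replicates of $n = 5000$. These
sizes were chosen so each check estimates its quantity with useful
precision on a single desk-class core.

## Limitations

* Two-level environments only; multi-level environments must be
  dichotomized (`dichotomize_environment()`), and unmapped rows are
  excluded per-environment, never listwise.
* The residual $t$-test examines means; invariance violations that move
  only higher moments are invisible to it (the variance-based companion
  test is intentionally not included).
* Pooled fitting assumes one logistic mechanism across environments; the
  test's conservativeness under parent-targeting interventions is
  documented above.
* The emulator reproduces marginals, one shared factor, and prevalences —
  not the true joint distribution of any cohort; conclusions about real
  data require the real data.
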