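---
title: "Offline distributional RL for hourly insulin dosing: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Offline distributional RL for hourly insulin dosing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insulinrl)
```

## The problem

After cardiac surgery most patients develop stress hyperglycemia in the
first 24 hours, and both hyperglycemia (>180 mg/dL) and hypoglycemia
(<70 mg/dL) are associated with worse outcomes. Care teams titrate
short-acting regular insulin hourly, usually with reactive sliding-scale
protocols that ignore patient-specific factors. `insulinrl` implements a
complete offline reinforcement-learning workflow for this problem: it
learns an hourly dosing policy from logged patient-hour trajectories,
evaluates it without deploying it, and characterizes how it differs from
the clinicians who generated the data.

The decision process is hourly: the state \(s_t\) is a normalized feature
vector (vitals, labs, comorbidities, ventilation and vasopressor status,
SOFA score, the prior four hours of glucose with hourly deltas and a
change-per-unit-insulin ratio); the action \(a_t\) is the regular-insulin
dose in units, continuous in learning and capped at 10 U/h; episodes span
at most 24 hours from the first glucose measurement.

## The reward

The per-step reward scores the glucose observed at the *next* hour — the
consequence of the dose — through a five-branch piecewise function that
plateaus at +0.2 on 140–180 mg/dL, descends linearly to −1 towards
70 mg/dL on the hypoglycemic side and towards 220 mg/dL on the
hyperglycemic side, and sits at −1 beyond; a quadratic penalty
\(0.001\,a_t^2\) discourages large boluses:

```{r}
curve(glycemic_reward(x), 30, 300, xlab = "glucose (mg/dL)",
      ylab = "reward", lwd = 2)
```

The function is continuous at every boundary and bounded in \([-1, 0.2]\).
Branch membership is half-open (\(70 \le x < 140\), and so on). Two
timing decisions are deliberate: the reward for \(a_t\) is computed from
the glucose at \(t+1\) (the only causal reading — the dose cannot affect
the measurement that preceded it), and the terminal hour's dose, whose
consequence is never observed, contributes no transition. Glucose outside
20–600 mg/dL is rejected as a data error rather than clipped: values
there are physiologically implausible and virtually always artefactual.

## The synthetic cohort

Access-restricted ICU databases cannot ship with a package, so the
package carries a generator of virtual post-cardiac-surgery cohorts that
reproduces the *structure* of such data — not their full physiology.
Glucose follows a linear-Gaussian stress model,

\[ G_{t+1} = \mathrm{clip}\big(G_t + d_t - s\,(a_t + 0.3\,a_{t-1}) +
\text{dextrose}_t + \text{rescue}_t + \varepsilon_t,\ 20,\ 600\big), \]

with a patient-specific stress drive \(d_t = d_0 \cdot 0.9^{t}\) drawn
uniformly from 0–11 mg/dL/h (diabetic patients get +3 and a higher
baseline), insulin sensitivity \(s\) uniform on 4–12 mg/dL per unit,
noise \(\varepsilon_t \sim N(0, 12)\) mg/dL, sporadic dextrose events,
and a dextrose rescue when glucose dips below 70 (clinicians treat
hypoglycemia). IV regular insulin acts fast, so a dose takes full effect
within its hour with a declared 30% carryover into the next.

The behaviour policy is a sliding scale: 0 U below 150 mg/dL, then
1/2/3/4/6/8 U per 40-mg/dL band, capped at 10 U, held when glucose is
below 90, with jittered deviations (±1 U mostly, occasionally +2 or +4)
and a 12% chance a due dose is skipped — the protocol non-adherence that
gives an offline learner room to improve. About 25 covariates are
simulated with severity (drive) reflected in SOFA, vasopressor use and
vitals, so learnable severity proxies exist; the latent truth is kept in
`sim_`-prefixed columns that are never features. Missingness is injected
per feature (labs ~15%, vitals ~3%, lactate 35% — deliberately above the
30% drop threshold so that rule always has work), and small fractions of
patients carry each exclusion flag.

Default rates were calibrated once, by simulation, to the cohort
structure the generator emulates: with 2000 patients roughly 47% have at
least one hour above 180 mg/dL and about 10% at least one below
70 mg/dL, and administered (nonzero) doses average about two units with
heavy right skew. What the generator does *not* model — insulin
compartment kinetics, meals, measurement timing irregularity, informative
missingness — bounds what passing tests can claim: they validate the
learning and evaluation machinery, not clinical performance on real
patients.

## From tables to transitions

`build_mdp()` chains the preprocessing stages:

* **Exclusions** remove patients who died within 24 h, have ambiguous
  medication records, lack glucose in the first three hours, or received
  other short-acting insulins; a patient with several flags is tallied
  once under the first criterion in that fixed order (the order is a
  declared convention for reproducible accounting).
* **Alignment** bins records into 1-h intervals (doses summed,
  measurements averaged), keeps the first 24 h, and re-indexes time so
  hour 0 is the first glucose measurement.
* **Missingness**: features missing in strictly more than 30% of
  training patient-hours are dropped ("over 30%" read literally);
  remaining gaps are forward-filled within patient; leading gaps that
  forward fill cannot reach are imputed by k-NN (k = 5) with distances on
  the fully observed features standardized by training min/max, donors
  drawn from the training split only. Whether the imputation model should
  see test data at all is a leakage question; everything here —
  missingness rates, donors, normalization statistics — is computed on
  the training split alone.
* **Glucose features**: lags 1–4 (backfilled with the earliest observed
  glucose — zero would be physiologically absurd and would distort
  normalization), hourly deltas, and the change-to-insulin ratio
  \(\Delta G_t / \max(a, 0.1)\), where the dose in the denominator is the
  one administered during the hour over which the change was measured
  (the previous row's action; the current hour's dose has not acted yet,
  and using it would leak the action into the state). The 0.1 floor keeps
  undosed hours finite.
* **Normalization** maps every feature to \([0,1]\) by training-split
  min/max, clipping out-of-range test values; constant features are
  dropped. The insulin column itself is the action, kept in raw units and
  excluded from the state (past doses reach the state through the lag-1
  dose and the ratio feature).
* **Transitions** pair consecutive hours into \((s_t, a_t, r_t, s_{t+1},
  \text{done})\) with actions clipped to \([0, 10]\) U.

Splits are at patient level (85/15 by default), and each model of the
multi-seed protocol trains on an 80% patient subsample.

## The learner

The agent is conservative Q-learning with an implicit-quantile critic and
a squashed-Gaussian actor over \([0, 10]\) U:

* The **critic** \(Z_\tau(s, a)\) embeds quantile fractions \(\tau\) with
  a cosine basis, merges them multiplicatively with a state-action trunk,
  and is trained by the quantile-regression Huber loss against
  distributional Bellman targets from a Polyak-averaged target network.
  Learning quantiles rather than the mean lets the critic represent
  outcome spread — relevant when identical-looking patients respond
  differently.
* The **conservative term** adds \(\alpha\,(\mathrm{logsumexp}_{a'}
  \bar Q(s, a') - \bar Q(s, a_\text{data}))\) with \(a'\) drawn uniformly
  on \([0,10]\) plus actor samples, where \(\bar Q\) averages a few
  sampled quantiles. This pushes value estimates down exactly where the
  data cannot support them — the central safety mechanism for offline
  learning with a narrow-therapeutic-index drug.
* The **actor** maximizes \(\bar Q\) of its own reparameterized sample
  with a small entropy bonus; recommendations use the deterministic mean,
  clipped and rounded half-up to integer units for clinical
  interpretability.
* **Return-weighted sampling** draws training transitions with
  probability proportional to a softmax (temperature 1 by default) of
  their episode's discounted return, keeping low-return behaviour from
  dominating the conservatism target; temperature \(\infty\) recovers
  uniform sampling and the mechanism is ablatable.

Published settings are the defaults: discount \(\gamma = 0.67\) (an
effective horizon of \(1/(1-\gamma) \approx 3\) h — glucose changes fast,
so distant rewards should not swamp immediate ones), batch 256, learning
rates \(10^{-4}\)/\(3\times10^{-4}\), three 512-unit hidden layers,
dropout 0.1. Everything the source description leaves open — the
conservatism weight, quantile sample counts, embedding dimension, Huber
threshold, target sync rate, OOD sample counts, entropy handling, the
sampling temperature — is an explicit `agent_config()` field with
defaults following the reference CQL and IQN formulations.

Two engines implement the gradient step: a compiled RcppArmadillo kernel
(the default) and a pure-R reverse-mode autodiff reference. They receive
identical random draws and are asserted equal to machine precision in the
test suite; the autodiff engine itself is checked against finite
differences. This dual-route design is why the hand-derived C++ gradients
can be trusted.

## Evaluation and selection

Policy value is estimated by fitted-Q evaluation: a plain MLP critic fit
by iterated Bellman regressions towards
\(r + \gamma\,Q(s', \pi(s'))\), value anchored at each episode's first
state, mean over episodes with a percentile-bootstrap 95% CI (10,000
resamples by default, resampling episodes — the independent unit — not
timesteps). The clinicians' value needs no model: their logged episodes
are on-policy, so the empirical discounted return is unbiased. The
multi-seed protocol trains one model per seed on an 80% training
subsample and selects the one with the highest CI *lower bound* on the
held-out test set — a pessimistic selection rule suited to offline RL's
seed-to-seed variance.

Because the simulator is available, the package can do what cannot be
done with retrospective clinical data: roll the selected policy out and
measure its ground-truth Monte-Carlo value. The acceptance suite asserts
both orderings — estimated (FQE above the clinicians' empirical return)
and ground truth (rollout value above the behaviour cohort's) — at a
deliberately reduced scale: 500 patients, 5 seeds, 10,000 gradient steps,
48-unit hidden layers, batch 96, a 16-dimensional quantile embedding,
6+2 conservatism action samples and \(\alpha = 0.1\), with a 48-unit FQE
critic. These sizes are the package's desk-scale study conditions: small
enough to run on one core in minutes, large enough for the orderings to
be stable. Three choices at this scale deserve a note. Learning rates of
\(10^{-3}\) compress the published schedule into the reduced step
budget. The conservatism weight drops from the default 5 to 0.1: with
48-unit networks, small batches and a behaviour policy whose beneficial
dose deviations are rare, a heavy logsumexp term suppresses exactly the
rarely-observed higher doses at hyperglycemia that the improved policy
needs, and the quantile loss is left to anchor in-data values. And
return-weighted sampling runs at temperature \(\infty\) (uniform): the
cohort's episode returns span about three reward units, so a unit
temperature would down-weight the sickest — most informative — episodes
roughly twenty-fold and starve the critic where dosing matters most; at
the published scale, with far more data, the mechanism's default
temperature of 1 is the ablatable setting it was designed to be.

## Descriptive analyses

`compare_policies()` evaluates the policy at every logged state and feeds
the descriptive statistics: time in range (closed interval
\([70, 180]\) mg/dL, closed because the hypo- and hyperglycemia
definitions are strict inequalities), per-patient cumulative dose
difference \(\Delta = \sum_t a_{t,\text{RL}} - a_{t,\text{obs}}\), TIR
and mean glucose by \(\Delta\) bin (the central \([-2, 2)\) bin is the
"model agrees" bin), mean doses by glucose range, exact agreement rate on
integer doses, disagreement-decile summaries, MAE between dosing schemes
with a two-sample t test on absolute errors, and permutation feature
importance — a model-agnostic stand-in for coalitional attribution that
measures how much the recommendation relies on each feature by the mean
absolute dose change under seeded column permutations. \(\Delta\) bins
are per-patient over the whole episode, and the glucose bin edges
(<70, 70–100, 100–140, 140–180, 180–200, 200–250, ≥250) are configurable
defaults, since no canonical edges exist.

## Numerical and degenerate-input choices

Half-open reward branches exactly as printed; dose rounding half-up
(2.5 → 3); ties in model selection resolve to the lowest index;
single-hour patients are skipped with a warning (no transition can be
built); patients without any glucose are dropped with a warning (the
exclusion filter should have caught them); hours with no recorded insulin
are dose 0, not missing; non-finite losses abort training with
diagnostics rather than silently producing a broken artifact; all
stochastic stages (simulation, splits, training, bootstrap, permutation)
take explicit seeds and restore the caller's RNG state.

## Known limitations

The simulator's linear-Gaussian dynamics have no insulin compartment, no
meals and no circadian structure, so absolute policy values in it do not
transfer to patients; only the machinery is validated. FQE shares the
function class with the policies it ranks and can flatter policies that
leave the data distribution — visible here as rollout values that are
lower than FQE estimates; the selection rule mitigates but does not
remove this, which is exactly why the ground-truth rollout assertion
exists. Desk-scale network sizes are far below the published 3×512
configuration; nothing here reproduces the published trained weights or
cohort-specific numbers that depend on credentialed clinical data.
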