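---
title: "Modeling multiple-response speed-accuracy tradeoff experiments with satdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling multiple-response speed-accuracy tradeoff experiments with satdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satdyn)
```

## The paradigm

In a speed-accuracy tradeoff (SAT) experiment, response accuracy is sampled
at multiple enforced response times, tracing the full time course of
information accrual instead of a single point on the speed-accuracy curve.
The multiple-response variant (MR-SAT) collects a judgment at every tone of
a within-trial sequence: listeners hear a sentence, and from 200 ms before
the onset of the sentence-final critical word a train of 15 tones (350 ms
apart, spanning a 5000 ms response window) paces their grammaticality
judgments. Participants begin by holding *both* response keys — the
conventional "undecided" signal — and switch to the single YES or NO key
once they have committed, with changes of mind allowed at any later tone.

The stimulus design crossed three construction conditions that vary the
distance between a subject noun and its verb — no interpolated material
(`NoInterp`), an interpolated object relative clause (`OR`), and
interpolated object + subject relative clauses (`OR+SR`) — over eight
sentence types: an acceptable and a verb-anomalous member per construction,
plus two control types whose anomaly sits *inside* the interpolated clause.
Forty-eight instances of each type are dealt into four lists of 96 (12 per
type per list).

This package simulates such experiments, scores them, fits the standard
exponential SAT model, and runs the group-level inference, so that every
stage of the analysis is testable without access to raw behavioral data
(none are publicly deposited for this paradigm).

## The model

Accuracy is measured per response lag by equal-variance signal detection,
`d' = z(hits) − z(false alarms)`, which controls response bias. The d'
time course is modeled as an exponential approach to a limit:

$$
d'(t) \;=\; \lambda\,\bigl(1 - e^{-\beta (t - \delta)}\bigr)\quad
\text{for } t > \delta,\ \text{else } 0,
$$

with asymptote $\lambda$ (d' units; representation quality/availability),
rate $\beta$ (1/s) and intercept $\delta$ (s; the time at which accuracy
first departs from chance). The two speed parameters $(\beta, \delta)$ are
the retrieval-dynamics signature: direct-access retrieval predicts
distance-*invariant* speed with distance-dependent asymptotes, whereas a
serial search predicts distance-dependent speed.

Condition structure enters through *parameter-sharing model
specifications*, named `<a>l-<b>b-<c>d` (e.g. `3l-1b-2d`): the counts give
the number of $\lambda$, $\beta$ and $\delta$ groups over the three
conditions. `1l-1b-1d` is the null model and `3l-3b-3d` the saturated one.
When a count is 2 the default grouping opposes `NoInterp` to the two
interpolated conditions, which is the substantive contrast (retrieval
needed or not); any grouping can be overridden explicitly.

```{r}
model_spec("3l-1b-2d")
```

## The generative model

The simulator is a first-class, tested component, built so that the d'
analysis is *exactly* invertible on its output:

* Each trial's latent discriminability is the SAT curve of its condition.
  While the curve is at 0 the simulated listener presses both keys; once it
  is positive, each lag's response is an independent equal-variance SDT
  draw: $P(\mathrm{YES}\mid\text{acceptable}) = \Phi(d/2 - c)$ and
  $P(\mathrm{YES}\mid\text{unacceptable}) = \Phi(-d/2 - c)$, so
  $z(\text{hit}) - z(\text{fa})$ recovers $d$ exactly. The placement is
  symmetric because it is the unique choice that makes the generative model
  and the d' analysis mutually inverse.
* Control-anomaly trials (anomaly inside the interpolated clause) follow a
  scaled-asymptote curve (default 0.8 λ), so simulated correct rejections
  grow exponentially but below the experimental conditions — the
  qualitative pattern observed empirically.
* Reading ability is drawn from the receptive-vocabulary prior
  Normal(96.41, 13.60) truncated to [74, 128], standardized with those same
  constants, and shifts *asymptotes only*, by `ability_slope_lambda`
  (default 0.3 d' per SD). This encodes the asymptote-only individual
  difference structure that the analysis is meant to detect.
* Between-participant heterogeneity: additive Normal(0, 0.2) jitter on
  asymptotes, Normal(0, 0.1) on intercepts, and lognormal (SD 0.2 on the
  log scale) jitter on rates. These magnitudes are of the order of the
  between-participant spread visible in published per-participant parameter
  tables, while keeping every simulated participant in a physiologically
  sensible range.
* `trials_per_cell` defaults to 48: a participant hears all four lists, as
  in the full set of experimental sessions. Recovery studies can lower it
  (12 = a single list).
* Two noise channels are available but off by default: a per-lag momentary
  response flip (`switch_prob`, a motor-slip channel) and a lognormal
  decision-time delay added to the intercept. They are off because the
  per-lag Bernoulli draws already produce response switching across lags;
  enabling either changes the generative claim (flips shrink recovered
  asymptotes toward chance deterministically).
* All randomness flows from one root integer seed; per-trial substreams are
  derived by hashing (seed, participant, trial), so enlarging a cohort does
  not reshuffle existing participants' data.

What the simulator does *not* emulate: acoustic properties of the stimuli,
serial dependence between successive lags within a trial (real listeners
rarely oscillate lag-by-lag), item-level difficulty variation, criterion
drift, lapses, and learning across sessions. Passing tests therefore show
that the *analysis machinery* is correct and well-calibrated under the
stated statistical structure — not that real data satisfy that structure.

## Scoring conventions

* Tone windows are half-open `[t_k, t_{k+1})`; key state is sampled at the
  window start (a release logged exactly at a tone time means "not held",
  with a 1 ns tolerance for floating-point time stamps).
* BOTH earns 0.5 yes-credit — this is what produces the observed ~50%
  early-lag correct-rejection rates — and NONE (no key held) is treated as
  missing, not as a guess.
* Hit/false-alarm rates are clipped to `[1/(2N), 1 − 1/(2N)]` (N = per-lag
  scorable trials), the standard edge correction that keeps d' finite and
  bounded by `2·z(1 − 1/(2N))`.
* The "averaged data" curve pools trial counts across participants before
  the z-transform (count pooling); a mean-of-per-participant-d' variant is
  available (`average = "mean"`). Count pooling is the default because the
  averaged curve is fitted as a single data set, which is most natural when
  its rates aggregate all trials.
* The empirical asymptote is the mean of the last four d' values.
* The first (pre-onset) tone is dropped by default from fitting and from
  correct-rejection profiles, leaving the 14 post-onset response points;
  this matches the number of per-lag values reported in published
  correct-rejection profiles, which strongly suggests the pre-onset lag was
  discarded. The choice is configurable (`fit_lags`, `drop_first_lag`).

## Fitting

The least-squares objective sums squared deviations between observed and
model d' over conditions and fit lags, all points weighted equally. The
optimizer is a portfolio: by default four algorithm families — Nelder-Mead
simplex and a Newton-type method (both with a quadratic box penalty),
L-BFGS-B, and the PORT routines (`nlminb`) — each launched from 10
uniform-within-bounds random starts, with the best run (smallest SSE; ties
to fewer iterations, then run order) polished by a tight bounded `nlminb`
pass. Runs are deterministic given (data, spec, config, seed): each restart
has its own derived substream, so a run with more restarts evaluates a
strict superset of the starting points of a smaller run.

Default box constraints: $\lambda \in [0, 6]$ d', $\beta \in [0.05, 6]$
1/s, $\delta \in [0, 3]$ s. An optional asymptote floor of 0.4 is provided
because published per-participant tables show several weakest-condition
asymptotes pinned at exactly 0.400, suggesting such a constraint in the
original workflow; the default floor is 0.

Two validity flags accompany every fit. `asymptote_overestimated` fires
when a fitted asymptote exceeds the *best* empirical asymptote among the
conditions sharing that parameter group by more than 1.0 d' (a shared
group legitimately compromises across its conditions, so it is judged
against the strongest of them), or sits at the upper bound.
`at_bound` fires when any parameter is within tolerance of a box
constraint. Flagged fits are recorded but excluded from model-comparison
summaries and parameter tables, mirroring the exclusion of participants
who cannot be fit by a model without asymptote overshoot.

```{r}
curves <- noiseless_curves(reference_params()$comm_3l1b2d)
fit_model(curves, "3l-1b-2d", fit_config(seed = 1))
```

## Model comparison and selection

Fit quality uses the parameter-adjusted $R^2$,

$$
R^2_{\mathrm{adj}} = 1 - \frac{SS_{\mathrm{res}}/(n-k)}{SS_{\mathrm{tot}}/(n-1)},
$$

with $k$ counting only the λ/β/δ groups. Nested models are compared by the
per-participant and averaged-data increase in adjusted $R^2$. The verdict
rule operationalizes the narrative convention of the field: an added
parameter group is accepted iff the averaged-data gain exceeds a threshold
(default 0.005) *and* a majority of non-excluded participants improve;
among justified models with no justified extension the fewest-parameter
model wins, with ties broken toward intercept over rate groups (the
conservative reading when the two speed parameters trade off). The
threshold and majority fraction are configuration constants, not claims
about any original analysis.

## Inference

Group-level analyses are linear mixed models with participant random
intercepts, fitted with `lme4` and tested with Satterthwaite-approximated
denominator degrees of freedom via `lmerTest`; grouping factors are
sum-coded so that covariate main effects are evaluated at the average
condition. Pairwise contrasts are paired t tests on per-participant values
with the |t| > 2 significance convention; a zero-variance difference is
reported with an infinite-t sentinel rather than an error.

Parameter tables carry one row per participant × quantity × *parameter
group* (not per condition): expanding a shared parameter into duplicated
per-condition rows would leave the random-intercept model with zero
residual variance. When a quantity has a single shared group (one value
per participant), the random intercept is unidentifiable and an ordinary
least-squares regression on the ability covariate is reported instead.
Ability scores are standardized within sample before entering the model.

## Numerical choices and problem sizes

* Convergence: relative objective tolerance 1e-10 in portfolio runs;
  polish at 1e-15. Noiseless round-trips recover bundled averaged-data
  parameter rows to well below three decimals.
* The grid-search cross-check of the optimizer uses a 0.01-step exhaustive
  grid on a single-condition problem, evaluated exactly via the algebraic
  expansion of the quadratic-in-λ objective.
* Calibration studies in the test suite use 100 simulated cohorts of 22
  participants (12 trials/cell for the recovery/selection study, the full
  48 for the ability-effect study) and a screening fit configuration (PORT
  + L-BFGS-B, 2 restarts, polished); these sizes give stable Monte-Carlo
  estimates while keeping the suite's runtime moderate.

A calibration finding worth knowing: with community-cohort-sized
parameters, the averaged-data adjusted-R² gain from the second intercept
is about 0.005 — the default acceptance threshold — and at 12 trials per
cell the per-participant gain for a sixth parameter must beat a ~2.7%
SSE-reduction penalty that the true intercept-gap effect only matches.
Selection between the one- and two-intercept three-asymptote models is
therefore near chance at single-list trial counts and becomes reliable
only with well-separated intercepts or full-design trial numbers; the
asymptote structure, by contrast, is selected robustly even at 12 trials
per cell. Ladder fits warm-start every model from the embedded solutions
of its nested ancestors, so a larger model's best SSE never exceeds a
nested model's and adjusted-R² deltas reflect data, not optimizer luck.

## Known limitations

* The per-lag independence assumption makes simulated within-trial
  response sequences noisier than real ones; real MR-SAT streams are
  strongly autocorrelated. None of the scoring or fitting steps depend on
  this, but simulated single-trial streams should not be used to study
  switching behavior itself.
* Fitted λ and δ estimates are correlated within participant; with very
  few trials per cell this can leak an asymptote-only individual
  difference into apparent (spurious) speed effects. At the full design
  size the leak is within the nominal type-I rate, which is exactly what
  the calibration suite checks.
* The Satterthwaite denominator degrees of freedom for a between-
  participant covariate depend on the random-effects structure; the
  package reports whatever the stated random-intercept model yields rather
  than targeting any particular printed df.
* No standard errors or CIs are attached to SAT parameters (none are
  conventional in this literature); bootstrap machinery is out of scope.
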