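# satdyn

Simulation and analysis of auditory **multiple-response speed–accuracy
tradeoff (MR-SAT)** experiments on memory retrieval during sentence
comprehension.

## The scientific problem

When a verb must be linked to a distant subject noun ("The book that the
editor admired **ripped**"), does the parser *search* memory — which
predicts slower retrieval the more material intervenes — or does it access
the subject *directly* through content-addressable cues, predicting
distance-invariant speed with distance-dependent accuracy? The SAT
procedure answers this by sampling accuracy at many enforced response
times: listeners judge sentence acceptability in time with a train of 15
tones (every 350 ms, starting 200 ms before the critical word, spanning a
5000 ms window), pressing both keys while undecided and a single YES/NO
key once committed.

Accuracy at each lag is the equal-variance signal-detection sensitivity
d′ = z(hits) − z(false alarms), and its time course is fitted with the
exponential approach to a limit

    d′(t) = λ (1 − exp(−β (t − δ)))   for t > δ, else 0

with asymptote λ (representation quality), rate β and intercept δ (the
retrieval-speed parameters). Hierarchically nested models — from a null
`1l-1b-1d` (one λ, β, δ shared by all three construction conditions) to the
saturated `3l-3b-3d` — are fitted by a multi-start bounded optimizer
portfolio and compared by the parameter-adjusted
R² = 1 − (SSres/(n−k)) / (SStot/(n−1)), per participant and for the
averaged data. The signature of direct-access retrieval is a preferred
model with three asymptotes but only two speed parameters (fast when no
retrieval is needed, slower but *constant* otherwise), and — across
individuals — reading-ability effects on asymptotes only.

The package provides, as testable modules: a stimulus-design generator and
a response-stream simulator with the exact statistical structure the
analysis assumes (so every stage runs without raw data, which are not
publicly deposited for this paradigm); stream → lag-code scoring; d′ and
correct-rejection profiles; model specification, fitting, and validity
flags; nested-model consistency reports and a preferred-model verdict; and
mixed-model group inference (participant random intercepts, Satterthwaite
df, |t| > 2 contrasts) with an ability covariate.

## Worked example

```r
library(satdyn)

spec <- design_spec()                   # 384 items, 4 lists x 96, 15 tones
cohort <- simulate_cohort(spec, cohort_params(n_participants = 22, seed = 1),
                          seed = 1)
curves <- dprime_curves(cohort$trials, spec)
ladder <- fit_ladder(curves,
                     c("1l-1b-1d", "2l-1b-1d", "3l-1b-1d",
                       "3l-1b-2d", "3l-1b-3d", "3l-2b-1d"),
                     fit_config(seed = 1, restarts = 2,
                                algorithms = c("port", "lbfgsb")))
print(ladder)
select_preferred(ladder)
round(ladder$models[["3l-1b-2d"]]$average$theta, 3)
```

Output:

```
SAT model ladder
  1l-1b-1d  avg adjR2 = 0.554; 21/22 participants usable
  2l-1b-1d  avg adjR2 = 0.958; 18/22 participants usable
  3l-1b-1d  avg adjR2 = 0.988; 19/22 participants usable
  3l-1b-2d  avg adjR2 = 0.996; 19/22 participants usable
  3l-1b-3d  avg adjR2 = 0.996; 19/22 participants usable
  3l-2b-1d  avg adjR2 = 0.996; 8/22 participants usable
Preferred model: 3l-1b-2d
  justified: 1l-1b-1d, 2l-1b-1d, 3l-1b-1d, 3l-1b-2d
lambda1 lambda2 lambda3   beta1  delta1  delta2
  2.700   1.425   0.844   0.777   1.186   1.594
```

Reading this: adjusted R² climbs steeply while asymptote groups are added
(0.554 → 0.958 → 0.988) and only marginally afterwards; the verdict
machinery accepts the second intercept (averaged-data gain > 0.005 and a
participant majority) but not a third speed parameter, returning the
three-asymptote, one-rate, two-intercept model that generated the data.
The averaged-data parameters sit close to the generating community-cohort
set (λ = 2.690/1.482/0.834, β = 0.779, δ = 1.266/1.579); many participants
cannot be fitted by the two-rate variant without overestimating their
asymptotes and are excluded from that model's summaries, mirroring the
exclusions reported for real cohorts.

The numbered drivers under `analysis/` run the same pipeline as a narrative
sequence (simulate → score → fit → select → infer), writing tables under
`results/`.

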