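# survcloak

Privacy-enhancing survival curves for per-site (federated) release.

Survival curves are a staple of biomedical reporting, but a raw
Kaplan–Meier plot can be disclosive: every step corresponds to a group of
subjects who experienced the event at that time, and when the group has
size one an adversary who can place an individual in the study learns
*that* they had the event and *when*. Censoring tick marks leak the same
way. In federated-analysis settings (where only aggregate results may
leave each data-holding site) a curve therefore needs to be transformed
before release. survcloak implements that release path end to end:
estimation, disclosure guards, anonymisation, per-site execution, and an
empirical harness for measuring how much an attacker can still learn.

## The method

The survival function is S(t) = Pr(T > t), estimated by the
product-limit (Kaplan–Meier) estimator over the distinct observed times
t₁ < t₂ < …:

    S(t_i) = Π_{j ≤ i} (1 − d_j / n_j)

with d_j events among n_j subjects at risk just before t_j. The released
curve replaces the raw staircase with one of three mechanisms:

- **LOESS smoothing** (the primary method): the (time, surv) points are
  smoothed by tricube-weighted local-linear regression. The span is
  chosen automatically by minimising the corrected Akaike information
  criterion for linear smoothers,

      AICc = log(σ̂²) + 1 + 2(ν + 1) / (n − ν − 2),

  where σ̂² = RSS/n and ν is the trace of the smoother's hat matrix.
  Smoothing removes the steps, so the timing and size of individual drops
  can no longer be read off the curve.
- **Probabilistic anonymisation**: seeded multiplicative Gaussian noise,
  specified as a percentage of each value, on the time and/or survival
  axis, followed by a monotonicity repair (times strictly increasing,
  survival non-increasing in [0, 1]).
- **Deterministic anonymisation**: each point moves to the centroid of
  its k nearest neighbours in the (time, surv) plane.

Every release suppresses censoring marks, passes a minimum-count
disclosure guard (defaults: 10 subjects, 5 events), and records its
method, parameters and seed. `federate_curves()` runs the same release
independently per site, so no information crosses site boundaries. The
evaluation harness (`leave_one_out_delta()`, `ablation_study()`,
`step_identifiability()`, `detect_inflections()`) implements the
leave-one-out adversary: compare releases with and without one subject
and try to localise that subject's event time.

## Worked example

```r
library(survcloak)

cohort <- veteran_like_fixture()      # 137 synthetic subjects, early-event skew
km     <- fit_km(cohort)
glance(km)
#>       n n_event n_censor median_survival
#> 1   137     125       12            110.

length(step_identifiability(km))      # times attributable to one subject
#> [1] 125

release <- privacy_curve(cohort, method = "loess")
glance(release)
#>   method site                   n_input n_points   span censor_marks_suppressed
#> 1 loess  veteran_like_synthetic     137      138 0.0652 TRUE
```

125 of the raw curve's 137 steps belong to a single subject — each one a
potential disclosure. The release is a smooth polyline (AICc-selected
span 0.065 here) carrying only (time, surv) pairs. The leave-one-out
check shows what an adversary gets from it:

```r
idx   <- which(cohort$time == step_identifiability(km)[60])[1]
leave_one_out_delta(cohort, index = idx)
#> Leave-one-out curve delta (method loess)
#>   sup-norm = 0.004134, mean |diff| = 0.001898 over 138 grid points
#>   removed subject: time 93.01, event 1
#>   raw new-drop time: 93.00776
#>   inflections (full curve): 6.149, 14.66, 19.02, 30.44, 41.69, 84.33, ...
```

The raw curves localise the withheld subject's event time exactly (the
"new drop" at 93.0), while the smoothed curve's nearest detected
inflection is more than 8 time units away — the attack the release is
designed to defeat.

A command-line wrapper over the same functions ships in
`inst/cli/survcloak.R`:

```sh
Rscript inst/cli/survcloak.R simulate --n 100 --seed 1 --output cohort.csv
Rscript inst/cli/survcloak.R curve --input cohort.csv --method loess \
    --output curve.json --plot curve.svg
Rscript inst/cli/survcloak.R federate --outdir out/ siteA.csv siteB.csv
```

Exit codes: 0 success, 2 validation error, 3 disclosure-control refusal.

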