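---
title: "Privacy-enhancing survival curves: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Privacy-enhancing survival curves: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survcloak)
```

survcloak turns subject-level right-censored survival data into curves
that are safe(r) to release from a data-holding site. This vignette is
the package's own account of the statistics it implements, the knobs
that matter, and the design decisions taken where the design was
genuinely open.

## The estimation model

For records $(t_i, \delta_i)$ with follow-up time $t_i \ge 0$ and event
indicator $\delta_i \in \{0, 1\}$, `fit_km()` computes the product-limit
estimator of $S(t) = \Pr(T > t)$,
$$\hat S(t) = \prod_{j : t_j \le t} \left(1 - \frac{d_j}{n_j}\right),$$
with $d_j$ events among $n_j$ subjects at risk just before the $j$-th
distinct observed time. Assumptions: right censoring only, independent
of the event process; record order carries no information. Conventions:

- censoring-only times are listed in the curve as well as event times —
  the smoothing step operates on exactly this grid, so it must match
  what a standard `survfit`-style object exposes;
- ties between events and censorings at one time count the events first
  (censored subjects remain in that time's risk set);
- no variance or confidence-interval estimation: only the point
  estimate is released, so only the point estimate is computed.

Raw curves are right-continuous step functions and are evaluated as
such; released (smoothed/anonymised) curves are polylines and are
evaluated by linear interpolation with constant extrapolation beyond
their endpoints.

## The release path

`privacy_curve()` is the single gate through which a curve leaves a
site: disclosure guard, estimation, anonymisation, clipping to $[0,1]$,
censoring-mark suppression, and full parameter/seed recording. The
disclosure guard refuses the request (with an error that names the rule
but echoes no data) when the dataset has fewer than `min_subjects`
subjects or `min_events` events. The thresholds are deployment
conventions, not statistical constants; the literature deliberately
leaves the minimum open, so both default values (10 and 5) are
configurable and documented as conventions.

`federate_curves()` applies the same release independently to each
site's data. The federation is an in-process contract — each site's
output is a pure function of that site's data — rather than a network
protocol; no transport, authentication or server integration is
implemented or simulated beyond that contract.

## LOESS smoothing with automated span selection

The primary mechanism smooths the curve points by local polynomial
regression. At each target $x_i$ the $q = \lceil \alpha n \rceil$
nearest neighbours (absolute distance on the raw time axis; the
predictor is univariate, so no standardisation) are fitted by weighted
least squares with tricube weights
$w(u) = (1 - |u|^3)^3,\; u = |x - x_i| / d_{\max}$, where $d_{\max}$ is
the distance to the window's furthest point (which therefore gets
weight exactly zero). The fit is linear in the response, so a hat
matrix $L$ exists; its trace $\nu$ is the effective degrees of freedom.
The span $\alpha$ is chosen by minimising the corrected AIC for linear
smoothers,
$$\mathrm{AICc} = \log \hat\sigma^2 + 1 + \frac{2(\nu + 1)}{n - \nu - 2},
\qquad \hat\sigma^2 = \mathrm{RSS}/n,$$
the small-sample form appropriate for the modest point counts of a
single survival curve.

Parameters and defaults:

| parameter | default | meaning |
|---|---|---|
| `span` | `"auto"` | fraction of points per window, in (0, 1]; `"auto"` = AICc minimisation |
| `degree` | 1 | local polynomial degree (1 or 2); the low-degree fit is the method's default posture |
| `interval` | [0.05, 0.95] | span search interval |
| `anchor` | `TRUE` | prepend (0, 1) to the smoothing grid so the smooth starts at full survival |
| `monotonise` | `FALSE` | running-minimum projection of the smoothed values |

Design decisions worth recording:

- **Exact search instead of a line search.** The fit depends on the
  span only through the integer window size $q$, so AICc is piecewise
  constant in the span and golden-section-style searches can stall on
  the plateaus. `select_span()` therefore enumerates every achievable
  $q$ in the interval and minimises exactly — deterministic, and at
  least as good as any grid or line search over the same interval. Ties
  break towards the larger window (more smoothing, hence more privacy).
- **Behaviour on noise-free staircases.** A KM staircase evaluated at
  its own jump points is essentially noiseless, so the likelihood term
  $\log\hat\sigma^2$ keeps rewarding smaller windows and the selected
  span tends to sit near the bottom of the interval; the automated
  smooth tracks the raw curve closely with small-amplitude wiggle. This
  is faithful behaviour of the criterion (an independent check with
  `stats::loess` under the same criterion and a golden-section search
  selects spans in the same regime), not an implementation artefact.
  Users who want visibly stronger smoothing can force a span.
- **Numerical guards.** $q$ is computed as
  $\lceil \alpha n - 10^{-9} \rceil$ so that $\alpha = q/n$ does not tip
  to $q+1$ through floating-point noise; $\hat\sigma^2$ is floored at
  $10^{-300}$ before the log so exactly-linear inputs select cleanly
  instead of crashing; windows whose weighted design is rank deficient
  (all x equal, or only zero-weight distinct points) raise a classed
  rank error; `AICc` is treated as undefined (infinite) for windows
  with $n - \nu - 2 \le 0$.
- **Clipping, not re-monotonising.** Smoothed values are clipped to
  $[0,1]$ but *not* forced monotone by default: the raw LOESS output is
  what the method releases, and silently projecting it would alter the
  released statistic. `monotonise = TRUE` applies the running-minimum
  projection for users who need a valid survival function.
- **Gaussian local fitting only.** No robustness (iteratively
  reweighted) iterations and no generalised cross-validation criterion:
  the automated criterion is AICc, and the fitting family is the plain
  weighted least-squares one.

## The two alternative mechanisms

**Probabilistic anonymisation** perturbs each selected coordinate $v$
to $v(1 + p/100 \cdot \varepsilon)$, $\varepsilon \sim N(0,1)$ i.i.d.
under a caller-supplied seed (time-axis draws first, then
survival-axis, so single-axis releases are reproducible from the same
seed). The mechanism statement "random noise as a percentage of the
value" does not fix a distribution; mean-zero Gaussian is the simplest
reading and is isolated in one function if a different law is ever
wanted. The repair step restores the survival-staircase shape: times
are clamped at zero, sorted, residual ties broken by a minimal offset
(strictly increasing); survival values pass through a running minimum
(the cheapest projection that preserves right-continuity) and are
clipped to $[0,1]$.

**Deterministic anonymisation** replaces each point by the
coordinate-wise mean of its $k$ nearest neighbours in the (time, surv)
plane, the query point included among its own neighbours ($k = 1$ is
the identity), distance ties broken by lower index for determinism.
Axes are deliberately not standardised before computing distances; on
survival curves the time axis therefore dominates, which matches how
the mechanism behaves when applied naively — including its known
weakness on skewed data, where with large $k$ points are pulled towards
the cloud's centre of mass ($k = n$ collapses the whole curve to one
point). One caution from testing: centroid replacement does *not*
always contract per-axis sample variance (a $k = 2$ counterexample
arises on random staircases); what always holds is the convexity
property — no output leaves the input range on either axis or moves
farther from the input centre of mass.

Differentially private release is out of scope: it requires per-user
privacy-budget accounting that the surrounding platform would have to
provide.

## Measuring what an adversary still learns

The adversary model is deliberately concrete: an attacker holds a
previously released curve and sees the release after one subject joins
(equivalently: before/after one subject is withheld). For raw curves
the attack succeeds by construction — `leave_one_out_delta()` reports
the "new drop" time, the earliest event time present in one curve's
drop set and not the other's, which for a singleton event equals the
subject's event time exactly. (Note that the two raw curves differ
*numerically* from the first event time onwards, because removing a
subject shrinks every earlier risk set; the attack signal is the new
drop, not the first numerical difference.)

For smoothed curves the analogous signal is a visible change of
curvature. `detect_inflections()` is a declared proxy for reading
inflections off a plot: compute second differences of the survival
values via divided differences (uneven grids are the norm), call a
value *salient* when its magnitude exceeds `sensitivity` times the
median absolute second difference, and flag a change point where a
salient value's sign differs from the previous salient one (the onset
of salient curvature counts as the first change point; sub-threshold
wiggle between equal signs is ignored; an absolute floor of
$10^{-12}\cdot\mathrm{range}(y)$ absorbs floating-point noise on
exactly-linear input). The default `sensitivity = 3` follows the usual
"several times the typical magnitude" salience convention: at 1, the
detector reports dozens of micro-wiggles of the close-tracking
automated smooth that no plot reader would call inflections. The
localisation tolerance used in the evaluation harness — an attack
"succeeds" when the nearest inflection falls within ±2 time units of
the true event time — is likewise a declared convention; the
qualitative claim being tested is only that smoothed-curve localisation
degrades materially from the raw curve's 100%.

`ablation_study()` completes the harness: draw a uniform random
subsample of a target size under a seed, release its curve, remove one
further random subject, release again, and report both curves with
their sup-norm/L1 delta — fully reproducible from the seed.

## The synthetic-data generator

`simulate_survival()` draws a latent event time and an independent
censoring time per subject and records the minimum with its indicator —
the independence assumption the product-limit estimator itself makes.
Defaults emulate the skew characteristic of survival data (more events
at earlier times): Weibull events with shape 0.8 (decreasing hazard),
scale 100, and exponential censoring at rate 0.0042, calibrated by
Monte Carlo to censor roughly 30% of subjects. `veteran_like_fixture()`
pins a 137-subject configuration shaped like the classic veterans
lung-cancer cohort — Weibull shape 0.9, scale 130 (times from days to a
few hundred days), exponential censoring at rate 5.5e-4 (~7% censored)
— under a fixed default seed so tests are stable. Only size and gross
shape are emulated; every value is synthetic.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: tied event times from integer-day
recording (synthetic times are continuous, so nearly every step is a
singleton), covariate-driven heterogeneity, informative censoring, and
administrative censoring at a common cutoff. Real registries with heavy
ties have fewer singleton steps and a coarser time grid; the
privacy-evaluation rates reported by the acceptance script are specific
to the stated synthetic conditions.

Problem sizes used by the test-suite and the acceptance script (chosen
as representative of the study conditions): 1000 random datasets of up
to 20 subjects for the exact product-limit oracle; 20 datasets of 10–50
points for the weighted-least-squares and grid-search oracles; 200
random staircases for the anonymisation monotonicity property; 100
seeded 137-subject replicates for the leave-one-out disclosure
experiment; one 137 → 50 ablation.

## Known limitations

- The released smooth is not a valid survival function by default (it
  can wiggle upwards locally); `monotonise` exists for consumers who
  need one.
- Local-linear fits track steep boundary trends well, so the smooth's
  final descent can mirror the raw curve's terminal drop; the privacy
  properties are weakest at the end of follow-up.
- The disclosure guard is a minimum-count check, not a formal privacy
  guarantee; no mechanism here removes disclosure risk, it only raises
  the cost of attribution.
- One curve per site: no pooled global curve is computed, which would
  require cross-site exchange of ordered event times.
- Interval and left censoring, time-varying covariates, and group
  comparisons beyond per-group release are out of scope.
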