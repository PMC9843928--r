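---
title: "Simulating ability-score and norm-referenced trial endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating ability-score and norm-referenced trial endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abilitysim)
```

## The question the simulation answers

Standardized developmental tests usually offer two scores for the same
performance.  Norm-referenced scores (here, the V-scale: mean 15, SD 3,
minimum 1) express standing relative to same-age peers and are the
natural diagnostic metric, but they are bounded below and lose variance
— eventually all of it — when a sample sits far below age expectations.
Person-ability scores (growth scale values, GSV), obtained from a Rasch
calibration and read off a raw-score lookup table, are interval-scaled
estimates of the person's latent ability and have no comparable floor
within the tabulated range.

`abilitysim` simulates the same parallel-arm trial under both scorings
and estimates the power (and type-I error) of each, across a grid of
age ranges, impairment levels and subdomains.  The point of the design
is that both endpoints are computed from the *same* simulated datasets,
so the power difference is attributable to the scoring alone.

## Generative model

A scenario fixes an age range (3–6 or 12–16 years, treated as the
half-open month ranges [36, 84) and [144, 204)), an impairment level
$k \in \{1,\dots,5\}$ SD below the normative mean (target V-scale
$15 - 3k$, floored at 1), and a subdomain.

**Mean.**  The generative GSV mean is anchored by the score tables at
the range midpoint (60 or 174 months): target V-scale band → mean raw
score of the band (midpoint, rounded half-up) → tabulated GSV.

**Spread.**  The classical identity $SD = SEM/\sqrt{1-r}$ converts each
normative age band's standard error of measurement and reliability into
a within-band SD.  Because the design range spans several bands, the
generative variance is that of the mixture

$$\sigma^2_{mix} = \sum_n w_n\sigma^2_n +
  \Big(\sum_n w_n\mu_n^2 - \big(\sum_n w_n\mu_n\big)^2\Big),$$

with $w_n$ the fraction of the month range each band covers and
$\mu_n$ the anchoring chain re-evaluated at that band's midpoint age.
The per-band means enter the dispersion term; where exactly to evaluate
them is not dictated by the anchoring idea, and the band midpoint is the
choice made here (an invariance test verifies that splitting a band into
identical halves leaves $\sigma_{mix}$ unchanged).

**Trial.**  $N = 24$ participants, 12 per arm.  The planning arithmetic
behind 24: the normal-approximation two-sample size
$N = 4(z_{1-\alpha/2}+z_{power})^2/d^2$ gives 66 (even-ceiling) for
$d = 0.8$, $\alpha = .05$, 90% power — the normal formula, not the
t-based one (which gives 68), is what reproduces 66 — and adjusting for
a baseline covariate with correlation $\rho = 0.8$ multiplies it by
$1-\rho^2 = 0.36$, even-ceilinged to 24 so the arms balance.  Baseline
and endpoint GSVs are bivariate normal with common SD $\sigma_{mix}$
and correlation 0.8; the treatment arm's endpoint mean is shifted by
$\Delta = 0.8\,\sigma_{mix}$ (zero in the null condition).  Using the
same $\sigma_{mix}$ in the shift keeps the standardized effect exactly
0.8; the alternative reading — deriving $\Delta$ from the midpoint-age
band's SD alone — would make the standardized effect vary by scenario.
Ages are uniform on the integer months of the range; everyone is
re-assessed 6 months later.  Allocation is fixed 12/12 rather than
Bernoulli: a balanced design is the only reading consistent with the
sample-size arithmetic.

**Scoring chain.**  The V-scale endpoint is derived per record: the
continuous GSV is rounded to the nearest tabulated GSV (ties upward) and
clipped into the table range; the tabulated GSV maps to a raw score —
when several raws share one GSV, the median raw, taking the lower of two
central values so the result stays an attainable count; the raw score
maps to a V-scale value in the band for the record's own age at that
timepoint (so everyone ages 6 months between assessments).  The GSV
endpoint is analyzed on the continuous drawn values by default: the
conversion step exists to produce V-scales, and rounding the GSV itself
is a separate measurement question, exposed as
`gsv_values = "tabulated"` for sensitivity analyses.

## Analysis model and decision rule

Each replication is analyzed by ANCOVA — least squares of endpoint on
intercept, arm indicator and baseline — with the two-sided arm p-value
from a t distribution on $n-3$ degrees of freedom.  A fit is
*degenerate* when the design matrix is rank-deficient (baseline
constant, as under a complete floor) or the residual variance is zero;
degeneracy is the operational trigger for "the ANCOVA could not be
performed".  A *complete floor* is an entire arm at the scale minimum at
both timepoints; the both-timepoints convention is deliberate (a
single-timepoint reading is arguable) and is kept as a separate
diagnostic from degeneracy since neither implies the other in every
direction.  The null is rejected only for a non-degenerate fit with no
complete floor and $p < .05$ strictly; degenerate and floored
replications count as failures to reject, which biases *against* the
V-scale endpoint only in the sense that a scale that cannot produce a
test cannot produce a rejection.

Power for a scenario is the rejection fraction over 5,000 replications
(10,000 for the null condition).  Both endpoint scales are computed from
the same replications, which also reduces the Monte-Carlo variance of
their difference.

A closed form for the GSV power exists and is used as a cross-check:
conditional on the realized arm–baseline correlation $r$, the ANCOVA
t statistic is noncentral t with $n-3$ df and noncentrality
$\tfrac{d}{\sqrt{1-\rho^2}}\sqrt{n/4}\sqrt{1-r^2}$; under randomization
$r^2 \sim \mathrm{Beta}(1/2,(n-2)/2)$, and
`ancova_power_closed_form()` integrates the conditional power over that
distribution.  The plug-in version ($r = 0$) overstates power by about
0.016 at this design — the cost of estimating the slope of a random
covariate — which is also why observed GSV power sits just under 86%
rather than at the naive 87.6%.

## The synthetic tables

The real instrument's conversion tables are copyrighted, so the package
generates structurally faithful stand-ins.  What the generator emulates,
per subdomain:

* a monotone raw→GSV map from 10 up to a maximum in 110–197, built as a
  random monotone step map with increments of ~0–3 GSV per raw score, so
  plateaus exercise the median-raw inversion;
* a normative median raw score that follows a saturating logistic in
  age, with per-subdomain midpoints and rates spread so
  expressive/receptive/motor-like subdomains saturate in early childhood
  (deep adolescent floors) while written-communication-like subdomains
  saturate late (moderate floors);
* an asymptote at 0.85 of the maximum raw score: real scales keep hard
  items above typical adult performance, which is what leaves headroom
  for above-average V-scales at all ages;
* V-scale bands cut at normal quantiles of the age-specific raw
  distribution (within-age SD = 9% of max raw at full development,
  scaled down with developmental level), lightly widened toward the
  floor (`tail_widening = 0.25`), with integer band edges forced to
  partition [0, max raw] in every 12-month age band over 24–216 months;
* SEM and reliability per age band, with reliability drawn uniformly in
  0.69–0.97 and the SEM derived from the within-age GSV SD the tables
  themselves imply (clamped into 2–9): SEM, reliability and band
  geometry describe one population in a real instrument, and breaking
  that consistency makes the simulated V-scale SD drift far from its
  nominal 3.

The default within-age SD keeps normative growth over one year at
roughly one within-age SD, so a one-year developmental lag costs about
2–3 V-scale points — the ratio that controls how much age heterogeneity
within an arm perturbs the V-scale endpoint.  Under these defaults the
generated study reproduces the qualitative structure the design needs:
about 96 of the 110 grid cells are feasible (deep-impairment bands are
genuinely absent at some ages and those cells are skipped and logged),
complete V-scale floors arise in a minority of scenarios with rates
spanning a few percent to near-total in the most extreme
adolescent conditions, and mild-impairment conditions lose little power
to the V-scale.

What the generator does **not** emulate: the real tables' exact band
widths, GSV spacing, age trends in SEM, or any copyrighted value; raw
distributions are symmetric around the median within an age (real ones
skew); and SEM/reliability are independent across age bands.  Passing
tests therefore demonstrate properties of the scoring *mechanism* —
floor formation, discretization, age-norming — not agreement with the
real instrument's numbers.  V-scale power values are
generator-dependent; GSV power is not (the analysis is equivariant under
affine rescaling of the GSV table, which a test verifies exactly).

## Numerical and reproducibility choices

* Integer months everywhere; age bands half-open [min, max).  The year
  ranges map to [12·min, 12·(max+1)) months, whose midpoints (60, 174)
  are exactly 5y0m and 14y6m.
* Midpoint raws round half-up; median raws take the lower-middle value;
  GSV rounding ties go upward; out-of-table draws clip to the extremes.
* Degeneracy tolerances are relative (residual variance below 1e-10 of
  the endpoint variance), so affine rescaling cannot flip a
  classification.
* One root seed drives everything; each scenario × condition gets a
  derived stream (seeds kept below 2³¹), so scenarios can be run in any
  order or in isolation with identical results.  Replications within a
  scenario are drawn vectorized from that scenario's stream; the
  vectorized ANCOVA is the same closed-form solve per column and is
  pinned against `lm()` and an explicit normal-equations oracle at 1e-9.
* The V-scale upper bound is fixed at 24 (mean 15 + 3 SD); ceilings
  never bind in these scenarios.

## Problem sizes

The shipped test suite runs the full grid at the study's replication
counts (5,000 effect / 10,000 null) once, plus a 50,000-replication
single-scenario run against the closed form; the whole suite takes a
few minutes on one CPU.  Smoke-level studies (`reps_effect` of a few
hundred) finish in seconds and are used for the deterministic-output and
consistency tests.

## Known limitations

* Scenario medians are taken across whichever subdomains are feasible in
  a condition, so adjacent impairment levels can compare different
  subdomain sets; with the V-scale nearly lossless at mild impairment,
  adjacent condition medians can tie or invert within Monte-Carlo noise
  even though the impairment gradient is real from level 3 on.
* No dropout, missing data, unequal allocation, or more than two
  timepoints; no rate-of-change analyses.
* GSV normality within a scenario is assumed, not derived from an item
  model; the Rasch calibration itself (and the GSV transformation
  constants) live inside the tables and are out of scope.
* The mixture SD inflates with the dispersion of band means across wide
  age ranges; whether that matches any particular real population is an
  empirical question the SEM tables alone cannot settle.
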