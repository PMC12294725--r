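---
title: "Acute dietary exposure to biogenic amines: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acute dietary exposure to biogenic amines: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baexposure)
```

# The assessment problem

Biogenic amines — histamine (HIS), tyramine (TYR), putrescine (PUT),
cadaverine (CAD) and tryptamine (TRY) — accumulate in fermented foods and
seafood through microbial decarboxylation of amino acids. Histamine is the
most acutely toxic of the five and is the only one with an established
health-based guidance value: a temporary Acute Reference Dose (ARfD) of
50 mg per day for healthy adults. `baexposure` implements the standard
two-tier assessment used in food-safety surveillance:

1. a **deterministic (point) screen**: worst-case exposure computed from a
   high percentile of consumption and a high percentile of concentration;
2. a **probabilistic assessment**: Monte Carlo propagation of fitted
   consumption and concentration distributions to a full acute-exposure
   distribution, from which exceedance probabilities and extreme percentiles
   are read off.

The package works from two tabular inputs: a concentration monitoring table
(one row per analyte measurement per food sample, possibly a non-detect
with its limit of detection, LOD) and a consumer-only consumption table
(one row per person-day, grams per day).

# Censored descriptive statistics

Monitoring data are left-censored: a sample below the assay's LOD is
reported only as a non-detect. Descriptive statistics follow the
surveillance convention:

* **detection rate** = detects / samples, per food × analyte stratum;
* **mean and P95 of the detects only** — non-detects are excluded, not
  substituted;
* a percentile is **suppressed** when fewer than `min_n` detects are
  available (default 10); reports render it as the `\` sentinel. Ten is a
  pragmatic floor: below it the empirical P95 is dominated by one or two
  order statistics. The threshold is configurable and affects only
  reporting and the point-assessment fallback, never the fitted models.
* the **total amine burden** of a food is the detection-weighted sum
  `sum(rate × mean-of-detects)` over the five analytes, which is identical
  to the mean over samples of the per-sample analyte sum with non-detects
  scored zero (an identity the test suite checks on synthetic data).

Percentiles throughout the package (descriptives, simulated exposure,
bootstrap) use the sorted-sample linear-interpolation estimator
(`stats::quantile` type 7, index *h* = (*n* − 1)*p* + 1). The choice is
immaterial at survey sample sizes but is fixed package-wide so that the
descriptive tables, the point assessment and the simulation report are
mutually consistent.

# Point assessment

The worst-case acute exposure for a food *i* and analyte *k* is

$$\mathrm{EXP} = \frac{\mathrm{Com}_i \times \mathrm{Con}_k}{1000}
\quad [\mathrm{mg/d}],$$

with Com the P99 of daily consumption (g/d) and Con the P95 of the
measured concentrations (mg/kg). When a stratum's P95 is suppressed the
maximum detect is used instead and the result is flagged (`con_stat_is_max`,
rendered as an asterisk in reports) — a deliberate conservative fallback
rather than dropping the stratum. For worst-case screens of the censored
sample itself, `worst_case_substitute()` sets every non-detect to its LOD
(the conservative substitution recommended for undetected values), which
can only raise summary statistics.

Exposure above the ARfD uses a **strict** inequality ("more than 50 mg/d"),
so boundary equality does not flag; comparisons are made on unrounded
values and only reports round to one decimal.

The **level of concern** (LOC) inverts the same formula: the concentration
at which a P99 consumer exactly reaches the ARfD,
LOC = ARfD / Com_P99 × 1000 (mg/kg). For histamine with ARfD 50 mg/d and
a 120 g/d high consumer this is 416.7 mg/kg. `count_above_loc()` counts
detected samples above it; the duality
`point_exposure(com, level_of_concern(arfd, com)) = arfd` holds to machine
precision and is tested.

# The mixture concentration model

Within one food category, the histamine concentration of a random sample is
modelled as a two-branch discrete mixture:

* with probability `p_detect` (the observed detection rate), a
  **lognormal** variate fitted to the detected concentrations;
* with probability `1 − p_detect`, a **Uniform(0, LOD)** variate standing
  in for the unknown concentration of a non-detect.

The lognormal fit is the closed-form maximum-likelihood estimate on logs:
`meanlog` is the mean of the log values and `sdlog` their standard
deviation with divisor *n* (the true MLE). At the sample sizes involved the
*n* vs *n* − 1 choice changes nothing visible, but it is fixed and
documented; an optimizer-based fit (`fitdistrplus`) serves as an
independent cross-check in the tests. A Shapiro–Wilk statistic on the log
values is computed and reported descriptively; it never gates the pipeline,
because distributional adequacy is a modelling judgement here, not a
filter.

Lognormal parameters are read and written on the natural-log scale
(`meanlog`, `sdlog`). Under this parameterization the consumption model
LN(2.62, 0.92) for fermented bean products implies a P99 of about 117 g/d,
consistent with the 120 g/d high-consumer figure used in the point
assessment — which is what pins the scale interpretation down.

`fit_mixture()` requires a single LOD per stratum and refuses mixed LODs
(the Uniform branch would otherwise be ill-defined); data with varying LODs
must be stratified first. The default LOD is 0.2 mg/kg, the only value
consistent with a Uniform(0, 0.2) non-detect branch, and is overridable per
record.

# Monte Carlo exposure simulation

`simulate_exposure()` draws, per iteration, one concentration from the
mixture and one consumption amount from the lognormal, **independently**
— no dependence structure between how much a person eats and how
contaminated their portion is — and forms exposure = consumption ×
concentration / 1000 (mg/d). Defaults follow standard practice for this
kind of assessment: 100,000 iterations, percentiles P25–P99.9, and 100
bootstrap resamples.

Design choices worth stating explicitly:

* **One-dimensional simulation.** Only variability is propagated. The
  bootstrap layer quantifies sampling uncertainty of the percentile
  estimators by resampling the simulated exposure vector (percentile
  bootstrap, 2.5th/97.5th percentiles of 100 replicate P97.5 values); it is
  not a second, parameter-uncertainty dimension.
* **Seeding.** The master seed spawns three fixed sub-seeds — one each for
  the concentration stream, the consumption stream and the bootstrap — via
  a deterministic integer map kept below 2³¹. Identical configuration gives
  bit-identical results; the test suite asserts this.
* **Strict exceedance.** `exceedance_probability()` counts exposures
  strictly greater than the ARfD, matching the point-assessment convention.
* **Analytic oracle.** On the detect branch, exposure is a product of two
  independent lognormals, itself lognormal with
  `meanlog = μ_conc + μ_cons − ln 1000` and
  `sdlog = √(σ_conc² + σ_cons²)`. Far above the non-detect branch's reach
  the tail probability is therefore `p_detect` times a lognormal upper
  tail, in closed form. `analytic_tail_oracle()` implements this and
  refuses thresholds the Uniform branch could materially reach (bounded by
  `p_nondetect × P(consumption > 1000·t/LOD)` against 1% of the main
  term). The simulator is validated against the oracle within three
  binomial standard errors, both for the published parameter sets and for
  randomized ones.

Under the published fermented-bean-products model
(0.7877·LN(2.52, 2.01) ⊕ 0.2123·U(0, 0.2), consumption LN(2.62, 0.92)),
the analytic mean factorization gives 1.548 mg/d and the closed-form
ARfD tail 0.40%; the cheese model
(0.2716·LN(0.84, 1.96) ⊕ 0.7284·U(0, 0.2), consumption LN(3.02, 0.62))
gives a mean of 0.1085 mg/d. The simulation reproduces these to Monte
Carlo accuracy. A percentile table from a published-parameter run is
monotone by construction of the empirical quantile function; the package
never reports a non-monotone row.

# The synthetic-data generator

Because the underlying survey microdata are not distributable, the package
carries a generator that emulates their statistical structure, so every
stage is testable end to end:

* true concentrations are lognormal; values below the LOD become
  non-detects (sharp-threshold censoring, no measurement-error model — the
  simplest mechanism consistent with a detect/non-detect dichotomy). The
  realized detection rate then *emerges* from censoring, converging to
  `Φ((meanlog − ln LOD)/sdlog)`;
* `lod_for_detection_rate()` inverts that relation, and the bundled study
  fixture uses it to tune its fermented-bean and cheese strata to realized
  detection rates near 78.77% and 27.16% at *n* = 2000 per stratum
  (binomial noise at that *n* keeps the realized rate within about two
  percentage points); three filler categories at *n* = 100 exercise all
  five analytes, suppression, and the fallback paths;
* consumption person-days are lognormal draws.

What passing tests on this fixture do **not** show: real monitoring data
have matrix-dependent LODs, inter-laboratory variation, non-lognormal
heavy tails, and correlated amine co-occurrence within samples (the
generator draws analytes independently). The fixture validates the
*machinery* — censoring bookkeeping, fitting, propagation — not the
adequacy of the lognormal family for any particular food.

One property of the method itself deserves emphasis: **fitting a lognormal
to detects only is biased** when censoring is substantial. The detects are
the upper tail of the true distribution, so the refit shifts `meanlog` up
and `sdlog` down, and with `sdlog` near 2 the implied mean can sit well
below the uncensored truth (about 19% low in the fermented-bean design).
The test suite asserts that this bias exists; any assessment built on
fit-to-detects inherits it. It is a property of the standard method, not a
defect of the implementation.

# Numerical and degenerate-input conventions

* Empty strata: detection rate is an error (undefined), mean/percentile of
  zero detects are suppressed (`NA`), never 0.
* Degenerate fits: constant samples are rejected (`sdlog` = 0 has no
  lognormal interpretation); fits need at least two values.
* `p_detect` ∈ {0, 1} are valid mixtures (pure Uniform / pure lognormal);
  the sampler never draws the absent branch.
* Rounding: detection rates and concentrations render at one decimal in
  report tables; all comparisons and stored values are full precision.
* Problem sizes in the shipped tests are chosen so the whole suite runs in
  seconds: 10⁵-iteration simulations where a published value is checked,
  2–4 × 10⁴ for property checks over several seeds, *n* = 2000 strata for
  parameter recovery.

# Known limitations

* Only histamine has an ARfD; the other four amines get descriptive and
  point-screen treatment only, with no probabilistic risk statement.
* The ARfD derives from a per-meal NOAEL but is applied per day, following
  regulatory practice for this assessment; no per-meal conversion is
  attempted.
* Concentration and consumption are sampled independently; if high
  consumers systematically prefer more- or less-contaminated products the
  exposure tails would shift.
* The Uniform(0, LOD) non-detect model is conservative for exposure means
  when the true sub-LOD mass concentrates near zero.
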