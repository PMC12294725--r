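# baexposure

Acute dietary exposure assessment of biogenic amines (histamine, tyramine,
putrescine, cadaverine, tryptamine) in food monitoring data, for
food-safety risk assessors working with left-censored surveillance tables
and consumer-only consumption surveys.

Fermented foods and seafood accumulate biogenic amines through microbial
decarboxylation of amino acids; histamine (HIS) is the most acutely toxic
and carries a temporary Acute Reference Dose (ARfD) of 50 mg/d for healthy
adults. The package implements the standard two-tier assessment:

* **Point (deterministic) screen** — worst-case acute exposure
  `EXP = Com_P99 × Con_P95 / 1000` (mg/d), with P99 daily consumption in
  g/d and P95 concentration in mg/kg (falling back to the maximum where a
  P95 cannot be reliably estimated), compared against the ARfD with a
  strict inequality. The **level of concern** inverts the same formula:
  `LOC = ARfD / Com_P99 × 1000` (mg/kg).
* **Probabilistic assessment** — the concentration of a random sample is a
  discrete mixture: with probability `p` (the detection rate) a lognormal
  fitted by maximum likelihood to the detected values, otherwise
  Uniform(0, LOD) for a non-detect. Acute exposure is simulated by Monte
  Carlo as `consumption × concentration / 1000` with independent lognormal
  consumption draws, yielding a percentile table, the probability of
  exceeding the ARfD, and a percentile-bootstrap 95% CI of the P97.5.

Supporting machinery: censored descriptive statistics (detection rates,
means/percentiles of detects with small-*n* suppression, detection-weighted
total amine burden), CSV readers/writers for monitoring, consumption and
summary tables, YAML/JSON model-parameter files, a closed-form lognormal
tail oracle validating the simulator, a synthetic study generator with a
sharp-LOD censoring mechanism, and an end-to-end pipeline driver.

## Worked example

Probabilistic acute histamine exposure for fermented-bean-product
consumers, under the published model (detection rate 78.77%, detects
lognormal with meanlog 2.52 and sdlog 2.01 on mg/kg, non-detects
Uniform(0, 0.2), consumption lognormal with meanlog 2.62 and sdlog 0.92 on
g/d):

```r
library(baexposure)

fb_conc <- mixture_model(0.7877, c(2.52, 2.01), lod = 0.2,
                         food_category = "fermented bean products")
fb_cons <- lognormal_params(2.62, 0.92, what = "consumption (g/d)")
fb_conc
#> Mixture concentration model for HIS in fermented bean products
#>   detect branch (weight 0.7877): Lognormal(2.5200, 2.0100)
#>   non-detect branch (weight 0.2123): Uniform(0, 0.2)
#>   model mean 73.83 mg/kg, sd 622.5 mg/kg

sim <- simulate_exposure(fb_conc, fb_cons, assessment_config(seed = 1))
sim
#> Monte Carlo acute dietary exposure simulation - fermented bean products
#>   100000 iterations, seed 1
#>   mean exposure 1.534 mg/d
#>      P25      P50      P75      P90      P95    P97.5      P99    P99.9
#>   0.0062   0.0809   0.4907   2.1462   5.0171  10.4380  24.3957 133.4474
#>   P(exposure > 50 mg/d) = 0.399%
#>   95% CI of P97.5: 10.18 - 10.88 mg/d
```

The mean consumer ingests about 1.5 mg histamine per day from fermented
bean products; the top 1% of consumption days exceed about 24 mg/d; and
0.4% of simulated days exceed the 50 mg/d ARfD — low for the general
population, non-negligible for high consumers. The closed-form check
`analytic_tail_oracle(fb_conc, fb_cons, 50)` gives 0.0040, in agreement.

The deterministic screen for cheese (P99 consumption 120 g/d, P95
histamine concentration 634.9 mg/kg):

```r
round(point_exposure(120, 634.9), 1)   # 76.2 mg/d  -> exceeds the 50 mg/d ARfD
round(level_of_concern(50, 120), 1)    # 416.7 mg/kg level of concern
```

A fully synthetic end-to-end run (generate → summarize → point-assess →
fit → simulate → LOC) is one call:

```r
fx <- make_paperlike_fixture(master_seed = 1)
manifest <- run_full_pipeline(fx$concentrations, fx$consumption,
                              config = assessment_config(seed = 1))
```

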