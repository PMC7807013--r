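# partmig

Carryover effects of migratory strategy in a partially migratory bird
population.

In partially migratory populations, long-distance migrants and residents
breed side by side in the same colonies, which makes it possible to ask
whether the migratory strategy an individual followed in winter carries over
into its body condition and breeding performance the next season. `partmig`
implements that analysis as a tested, reusable pipeline for movement and
behavioural ecologists:

1. **Strategy classification.** Each *bird-year* (one individual in one
   breeding season, labelled by the breeding calendar year) is classified as
   migrant, resident or unknown from three evidence streams covering the
   preceding winter window (01 Nov–15 Jan, inclusive):
   * winter resightings in the breeding areas → resident (a
     wintering-ground sighting → migrant);
   * geolocator fixes: resident iff no window fix south of 36° N, migrant
     iff ≥ 2 window fixes south of 23° N;
   * feather δ¹³C of winter-grown primaries: migrant iff δ¹³C > −20 ‰
     (strict), never resident — some migrants moult before departure, so
     depleted values are uninformative.
   Streams are reconciled conservatively: any resident-vs-migrant
   contradiction yields *unknown* with a conflict flag. A built-in
   sensitivity analysis reruns everything at cutoff ± 0.5 ‰.
2. **Phenology reconstruction.** First-egg dates are observed, back-calculated
   as hatch date − 32 days, or estimated by inverting a linear mixed-model
   calibration of chick wing chord on known age (valid 14–30 days, nest
   random intercept). A nest is successful iff ≥ 1 chick exceeds 20 days.
3. **Condition index.** Raw condition is mass/P8 (g · mm⁻¹). Relative
   condition is the residual from a penalized cyclic-spline GAMM of z-scored
   mass/P8 on day-of-year with a sex term and bird-identity random
   intercept: condition relative to the population mean for that sex and
   date. Captures strictly before 02 May form the *pre-incubation* subset.
   The same smoother handles seasonal NDVI pixel series by area.
4. **Inference.** Eight response analyses (year-round and pre-incubation
   condition, first-egg date, clutch size, fledgling count, nest outcome,
   fledging probability, brood chick condition) run through all-subsets
   model selection with AICc — the final model is the fewest-parameter
   member of the ΔAICc ≤ 2 set. Clutch size uses a from-scratch
   **Conway–Maxwell–Poisson** regression
   (P(Y=y) ∝ λ^y/(y!)^ν, log link on λ, ν estimated by ML) because clutch
   sizes are underdispersed; fledging probability uses QAICc with ĉ from the
   global binomial fit; strategy × area interactions get single-step
   post-hoc contrasts.
5. **Synthetic cohort generator.** `generate_cohort()` draws a full
   observation set (captures, resightings, fixes, feathers, nests, chicks)
   with known ground truth, so every stage is testable by parameter
   recovery, null calibration and power simulation.

## Worked example

```r
library(partmig)

cohort <- generate_cohort(sim_config(seed = 42))
cohort
#> Synthetic partially migratory cohort
#>   individuals: 100  bird-years: 500
#>   captures: 1043  resightings: 290  fixes: 686
#>   feathers: 263  nests: 190  chick rows: 248

report <- run_pipeline(cohort)
report
#> Partial-migration carryover analysis
#>
#> Strategy calls (adult, determined): 282 bird-years ( 138 migrant / 144 resident )
#> Conflicting bird-years: 1
#>
#> Final models:
#>   cond_yearround       strategy + area + strategy:area
#>   cond_preincubation   strategy + area + strategy:area
#>   first_egg            area
#>   clutch_size          1
#>   n_fledglings         1
#>   nest_outcome         1
#>   fledging_prob        strategy + area + strategy:area
#>   chick_condition      1
#>
#> Funnel:
#>                           stage    n
#>        bird_years_with_evidence  336
#>           bird_years_determined  282
#>     adult_bird_years_determined  282
#>                           nests  190
#>                  captures_total 1043
#>                  captures_adult 1041
#>    condition_rows_with_strategy  583
#>  condition_rows_after_exclusion  467
#>    condition_rows_preincubation  191
#>             nests_with_strategy  115
#>           nests_after_exclusion  101
```

The generator's truth contains a migrant condition deficit before incubation
in the poorer area only, no strategy effect on any breeding parameter, and
an earlier mean laying date in the poorer area — and that is what the final
models recover: the strategy × area interaction survives selection for the
condition analyses, `first_egg` keeps only `area`, and the breeding-success
analyses collapse to the null model (the `fledging_prob` interaction here is
selection noise on one seed; the null-calibration test quantifies it).
Pipeline products are tidyverse-friendly throughout:

```r
glance(report$selection$clutch_size)
#> # A tibble: 1 × 4
#>   criterion n_models  chat final
#>   <chr>        <int> <dbl> <chr>
#> 1 AICc            10    NA 1

report$posthoc                      # single-step contrasts, if interaction
autoplot(report$condition)          # seasonal condition smooth per sex
autoplot(report$selection$cond_preincubation)
```

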