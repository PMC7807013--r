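---
title: "Classifying migratory strategy and testing its carryover effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying migratory strategy and testing its carryover effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(partmig)
```

`partmig` analyses carryover effects of migratory strategy in a partially
migratory falcon population breeding in two areas of differing primary
productivity. This vignette is the package's own account of the methods: the
models and their assumptions, the tunable constants and why they default as
they do, what the synthetic generator does and does not emulate, the
numerical choices, and the design decisions taken where the problem was
genuinely open.

## 1. Strategy classification

The unit of classification is the **bird-year**: an individual in one
breeding season, whose strategy is decided by the *preceding* winter. The
winter window runs from 01 November of the previous calendar year to
15 January of the breeding year. Both boundaries are treated as inclusive:
the window is defined with a deliberate buffer around the earliest known
departures and returns, and an observation on the boundary date is still
inside that buffer.

Three evidence streams contribute verdicts, each deliberately asymmetric:

* **Resightings.** A bird seen in a breeding area inside the window is a
  resident that season; in-area winter records can never indicate a migrant.
  Records flagged as wintering-ground sightings (column `wintering_ground`)
  yield migrant verdicts instead.
* **Geolocator fixes.** Resident iff *no* window fix lies south of 36° N;
  migrant iff at least two window fixes lie south of 23° N; a track that
  does neither (intermediate latitudes) is unknown. A resident call
  requires at least one fix inside the window — absence of data is not
  evidence of residency. Whether the two southern fixes must come from
  distinct days is unspecified in the field protocol; here any two window
  fixes qualify.
* **Feather δ¹³C.** Winter-grown primaries with δ¹³C strictly above
  −20 ‰ indicate sub-Saharan moult origin, hence a migrant. The stream
  never calls residents: a fraction of migrants moult those feathers before
  departure and carry the breeding-ground signature, so depleted values are
  uninformative about strategy. A feather collected in breeding year *Y* is
  assigned to the winter preceding season *Y*.

`reconcile_strategies()` combines per-stream verdicts with a conservative
policy: unanimity among informative verdicts gives the strategy; no
informative verdict gives unknown; a resident-vs-migrant contradiction gives
unknown with a conflict flag and both pieces of evidence retained. The
field data this design mirrors contained no documented conflicts, so no
precedence rule among streams exists to copy; surfacing conflicts rather
than resolving them silently is the package's own choice, and the conflict
count is part of the report. `sensitivity_analysis()` reruns the isotope
stream (and reconciliation) at cutoff − 0.5, cutoff, cutoff + 0.5 ‰; because
the migrant rule is a strict threshold, the migrant set can only shrink as
the cutoff rises, which the tests assert as a set-inclusion property.

First-year birds are retained through classification but excluded from the
fitness analyses, which are defined for adults.

## 2. Phenology reconstruction

First-egg dates are assigned with a fixed preference order and a recorded
provenance tag:

1. `observed` — seen directly;
2. `backcalc` — first hatch date minus exactly 32 calendar days (laying
   plus incubation treated as a constant; incubation-length variation is a
   known limitation);
3. `wing_estimated` — chick age estimated by inverting a wing-growth
   calibration, hatch = measurement date − round(age), then the 32-day rule.

The calibration is a linear mixed model of wing chord on known age with a
nest random intercept, valid for ages 14–30 days (growth is non-linear
outside; out-of-window measurements are excluded with a logged count, and
inverted ages falling outside the window are flagged `extrapolated`).
Prediction uses fixed effects only, since a new chick's nest effect is
unknown. Ages are rounded to whole days before date arithmetic because
dates are day-resolution. The calibration may legitimately use years that
are excluded from inference (it is a measurement model, not a fitness
analysis).

A nest is successful iff at least one chick reaches an age *strictly*
greater than 20 days, and the fledgling count is the number of such chicks,
applied to the best available age bound (last seen alive). Brood condition
is mass/P8 averaged over siblings.

## 3. Condition index

Raw condition is mass divided by P8 length, separating dynamic mass from
structural size. The relative index comes from a generalized additive mixed
model fitted by `mgcv`: z-scored mass/P8 against a cyclic penalized
regression spline of day-of-year, a sex term, and a bird-identity random
intercept (random-effect basis), smoothing parameters selected by REML, the
backend default. Choices worth making explicit:

* **Cyclic basis.** Condition is a year-round quantity; a cyclic spline
  (knot wrap at the year boundary) avoids a spurious 01 January
  discontinuity that a default thin-plate basis would allow.
* **z-scoring before smoothing.** The index is used comparatively;
  residuals on the z scale make effect sizes across analyses commensurate.
  A constant shift in mass (at fixed P8) leaves the index unchanged.
* **Sex as an offset by default.** Whether sex should enter as an offset or
  as separate per-sex smooths is open; the default is one shared smooth
  plus a parametric sex offset (`sex_as = "by"` switches to per-sex
  smooths). With a single sex in the data the term is dropped with a
  warning.
* **Pre-incubation cutoff.** Captures strictly before 02 May of their year
  form the pre-incubation subset, the window where a winter carryover
  effect is most plausible before breeding effort dominates. The source
  protocol states the peak of mean female condition as 02 May in one place
  and draws the cutoff line at 01 May in another; "strictly before 02 May"
  and "through 01 May" are the same set, and that is what is implemented.
  The cutoff is a fixed configured date, not re-estimated per dataset, so
  the subset definition is reproducible.
* **All years enter the smoother.** The condition model uses every adult
  capture, including years excluded from inference; the exclusion applies
  to the fitness models only. This asymmetry is intentional: the smoother
  is a population reference curve, and dropping a year would change the
  meaning of everyone else's residuals.

The same machinery fits seasonal NDVI pixel series: per-area cyclic smooths
with a pixel random intercept, parameterised as a shared smooth plus an
ordered-factor difference smooth so that the difference smooth's approximate
test directly addresses "do the areas' seasonal trends differ?", and
per-area peak dates read off the fitted population-level trend.

## 4. Inference: CMP, AICc and the Δ2 rule

**Conway–Maxwell–Poisson.** Clutch sizes are underdispersed; a Poisson
model would overstate their variance and distort model ranking. The CMP
density P(Y=y) ∝ λ^y/(y!)^ν adds a dispersion parameter ν (ν = 1 is
Poisson, ν > 1 underdispersion). The normalizing constant
Z(λ, ν) = Σ λ^j/(j!)^ν is evaluated by truncated series in log space: terms
are accumulated until the running term drops below 10⁻¹² of the sum past the
mode (near λ^{1/ν}), with the truncation tail checked. The hard cap is
100 000 terms — generous because small ν pushes the mode far out (λ = 20,
ν = 0.3 has its mode near 21 500) — while regression fits bound the mode
below 300 through optimizer guards, keeping each likelihood evaluation
cheap. `fit_cmp_regression()` maximizes the likelihood over (β, log ν) by
BFGS from Poisson-GLM starting values; standard errors come from the
observed information, with the SE of ν obtained by the delta method. With
ν fixed at 1 the fit reproduces Poisson regression, which the tests assert
to coefficient-level accuracy; the pmf itself is checked against an
independent brute-force series oracle. Degenerate zero-variance counts are
flagged: the likelihood then flattens as ν grows and the estimate is large
but finite.

**Criteria and parameter counting.** AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1).
QAICc (fledging probability) divides −2ℓ by ĉ and adds one parameter for ĉ,
where ĉ is Pearson χ²/df from the *global* binomial model, floored at 1 and
applied to every sub-model. One counting convention holds across a
candidate set: fixed coefficients, plus one per variance component
(residual, random intercept), plus one for ν, plus one for ĉ. Gaussian
mixed models are fitted by maximum likelihood, not REML, so that AICc is
comparable across fixed-effect structures.

**Selection.** From each global model, every sub-model respecting
marginality (no interaction without both main effects) is fitted and
ranked. The final model is the fewest-parameter member of the ΔAICc ≤ 2
set, ties broken by the better criterion value. Model averaging is
deliberately not performed: the candidate sets contain interactions, whose
averaged coefficients are not interpretable. Non-convergent sub-models are
dropped with a log entry.

**Post-hoc contrasts.** When the final model retains strategy × area, the
within-area strategy contrasts and within-strategy area contrasts are
tested jointly with a single-step max-t adjustment (multcomp). The specific
adjustment used in the original field analysis is not documented beyond the
package name; the single-step joint-distribution adjustment is this
package's documented stand-in, and the tests treat it as such (dominance
over raw p-values, type-I calibration, localisation of a one-area effect) —
not as a reproduction of any particular printed p-value.

**Covariates** are z-scored (capture date, first-egg date), and capture
date enters the condition models linearly — it is listed among fixed
effects, and the seasonal shape has already been removed by the smoother.

## 5. The synthetic cohort generator

`sim_config()`/`generate_cohort()` define the study conditions under which
the pipeline is validated. Defaults, chosen once:

* 100 individuals × 5 breeding seasons (2014–2018) → 500 bird-years,
  matching the scale at which classifier recovery is asserted;
* two areas, a richer late-breeding one and a poorer early-breeding one
  (mean first-egg day-of-year 118 vs 107, SD 10 days);
* P(migrant) = 0.7 — at least ~70 % of individuals in such populations are
  expected to be migratory — with a 0.1 per-year switching probability, of
  the order of the switch frequency observed among multi-year individuals;
* feather δ¹³C at −23.5 ‰ (breeding-ground moult) vs −16.5 ‰ (Sahelian),
  common SD 1.2 ‰, placing the −20 ‰ cutoff between well-separated modes,
  with a 0.15 pre-moult contamination fraction among migrants so the
  classifier's migrant-only asymmetry actually matters in tests;
* winter fixes near 14.5° N (SD 1°) for migrants and near 37.2° N for
  residents, with transit fixes linearly interpolated outside the window;
  the generator guarantees the structural invariants the classifier relies
  on (no resident window fix south of 36° N; ≥ 2 southern fixes per tracked
  migrant winter);
* clutch sizes CMP with λ = 4.2, ν = 2.5 and log λ declining at −0.08 per
  SD of first-egg date; wing growth with slope 5 mm/day, intercept −10 mm,
  nest SD 3 mm, residual SD 4 mm;
* adult condition 2.9 g/mm baseline with a seasonal cosine (amplitude
  0.15, peak day 122), +0.08 for females, +0.05 in the richer area,
  individual SD 0.05, residual SD 0.08, and a migrant deficit of 0.10
  applied only before 02 May and only in the poorer area — the short-term,
  area-specific carryover signal the pipeline is meant to detect. All
  strategy effects on breeding parameters default to zero, the null the
  field data supported, and are switchable (`effects`) for power studies.

The fraction of bird-years with nests and the capture effort per period are
not constrained by any source and are free parameters (defaults 0.7 and
4 occasions × 0.5).

What the generator does **not** emulate: light-level measurement error and
geolocator failure modes (fixes are consumed as clean positions), laboratory
isotope error structure beyond a common Gaussian SD, observation-process
detail beyond per-stream detection probabilities, density dependence,
survival/recruitment, and raster NDVI imagery (a separate
`simulate_ndvi_series()` provides pixel series with known peaks). Passing
recovery tests on this cohort therefore demonstrates that the pipeline's
logic and estimators are correct under the stated data-generating
assumptions — not that real field data meet those assumptions.

## 6. Problem sizes and tolerances used in validation

The test suite asserts, among others: CMP/Poisson equivalence at ν = 1 to
10⁻¹²; pmf agreement with a brute-force oracle to 10⁻¹⁰; normalization to
10⁻⁹ across λ ≤ 20, ν ≥ 0.3; ν recovery within 2 SE in ≥ 90 of 100
replicate fits at n = 500; classifier accuracy ≥ 95 % with zero
migrant-called-resident errors on the default 500 bird-year cohort;
variance-component and sex-offset recovery of the condition smoother at
n = 566 captures; retention of a 1-residual-SD area-specific deficit by the
inference layer in ≥ 70 % of 50 replicates; and a majority-null outcome for
strategy terms over 50 replicates when all strategy effects are zero. The
simulation sizes (pixel counts, replicate numbers) are the package's chosen
validation scale: large enough for the binomial bounds quoted, small enough
to keep the suite quick to run.

## 7. Known limitations

* The conflict policy and the stream-combination rule are documented
  choices, not field-validated ones; populations with systematic stream
  disagreement need a different reconciliation.
* The 32-day back-calculation ignores incubation-length variation, and the
  wing inversion inherits any miscalibration of the growth model outside
  14–30 days.
* ĉ from the global model is standard QAIC practice but can overcorrect
  when the global model is itself misspecified.
* The CMP regression uses a single dispersion ν; dispersion covariates are
  out of scope.
* Bird-years with no winter evidence are unknown and drop out of fitness
  analyses; the funnel log reports how many, but no missingness model is
  attempted.
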