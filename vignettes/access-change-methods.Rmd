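---
title: "Measuring changes in adolescents' drive-time access to confidential family planning care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring changes in adolescents' drive-time access to confidential family planning care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r}
library(txaccess)
```

## The measurement problem

Minors' ability to obtain contraception confidentially depends on two
independent mechanisms. Clinics funded by the federal family-planning grant
program must let minors consent to services regardless of state law, so any
funded clinic within reasonable travel distance provides confidential access.
Separately, some states have their own statutes that let all minors consent
to contraceptive care and guarantee confidentiality, so adolescents in those
states keep access even with no funded clinic nearby.

When a regulatory change causes a large set of clinics to leave the funded
network between two observation years ("epochs", here labelled 2018 and
2020), the question is: *which census tracts lose their last confidential
option, and how many 15- to 17-year-olds live there?* `txaccess` implements
that measurement end to end, plus a synthetic-geography generator with
planted effect structure so every stage can be validated against known truth
without external data.

## Pipeline stages

### 1. Roster differencing (`deduplicate_roster()`, `classify_membership()`)

Administrative clinic directories contain duplicate records. A clinic's
identity key is its normalized name (case, punctuation and whitespace folded)
plus coordinates rounded to 4 decimals; later records with a repeated key are
dropped and reported separately. Differencing the deduplicated epoch rosters
labels each clinic `left`, `stayed`, or `joined`. Affiliation is classified
from name patterns and registries with precedence crisis-pregnancy-center >
Planned Parenthood > FQHC > other, and `program_change_summary()` reports
exits, entries and net loss with both raw-record and deduplicated
denominators (directory reports commonly quote percentages against raw
record counts).

### 2. State law (`classify_state()`)

A state is *protective* when its statute lets **all** minors consent to
contraceptive services **and** guarantees confidentiality. The `expanded`
variant additionally counts states where consent is granted at physician
discretion; it drives the `expanded_law` sensitivity mode. Classification is
a pure function of the law table, so alternative codings are one data frame
away.

### 3. Drive-time catchments (`road_network()`, `tract_within_drive()`)

Each tract is represented by the population-weighted centroid of its 1–9
population sub-units (block-group analogues). Travel time from centroid to
clinic is: snap each point to its nearest road-network node (straight-line
distance converted to minutes at `access_minutes_per_unit`), plus the
shortest path over the network (Dijkstra, via igraph), plus the clinic-side
snap. A tract is in the catchment when at least one clinic is within the
threshold, **inclusively**; the default threshold is 30 minutes, the Medicaid
maximum-reasonable-travel standard for medical care. Networks may be planar
or lon/lat (haversine); with no network, a straight-line fallback applies.
`min_travel_time_multi()` evaluates both epoch rosters in one pass, sharing
the snapping and the shortest-path matrix.

### 4. Access change (`classify_access()`)

Per epoch, a tract has access iff it is in a funded clinic's catchment OR
(in `primary` mode) lies in a protective state. The two epochs combine into
a four-category change variable: `lost`, `maintained`, `gained`, `never`.
`catchment_only` ignores state law; `expanded_law` uses the expanded
protective set. The Medicaid-enrolled population aged 15–17 is estimated as
Medicaid minors × the tract's proportion of minors aged 15–17, rounded half
up; `youth_at_risk()` totals the 15- to 17-year-olds in `lost` tracts and
splits them by Medicaid enrolment, since Medicaid-enrolled youth may retain
confidential access through Medicaid's own statutes.

### 5. Statistics (`univariate_or()`, `segmented_regression()`)

The characteristics analysis contrasts `lost` versus `maintained` tracts
(tracts that never had or that gained access are excluded). Continuous
covariates are binned into quartiles at their empirical 25/50/75 percentiles
(ties go to the lower bin; missing values are dropped per covariate). Each
odds ratio is the 2×2 cross-product with the Wald interval
`exp(log OR ± z √(Σ 1/cell))` — for a binary predictor this equals the
exponentiated coefficient of a univariate logistic regression, which
`stats::glm()` cross-checks in the test suite.

The national time trend is an interrupted time series: ordinary least
squares on `count ~ year + post + post:year` with `post` indicating years at
or after the breakpoint. Reported are the per-segment slopes with 95%
intervals from the coefficient covariance, using the t distribution on the
residual degrees of freedom (with ~15 annual points the normal approximation
under-covers). Each segment needs at least two
years — the minimum that defines a slope — so a design whose post-change
segment is only two years remains admissible.

## The synthetic generator

`generate_scenario()` builds a seed-reproducible national geography: states
on a grid (each assigned a census-style region and a law status drawn from a
fixed national mix of protective / no-law / limited / physician-discretion
statutes), tracts with population sub-units, a grid road network, and two
epoch clinic rosters where exit probability depends on affiliation (Planned
Parenthood sites exit almost surely; FQHCs rarely; independents in between)
and entrants arrive at a low rate. Duplicate records are injected at a small
rate so the deduplication stage has real work.

Two design choices matter for validation:

* **Outcome-conditional covariate planting.** Whether a tract loses access
  is decided by actual geography: which clinics left, and what remains within
  30 minutes. Covariates are then drawn *conditional on* the realized
  lost/maintained status, with within-group distributions chosen so each
  covariate's lost-vs-maintained 2×2 odds ratio equals its planted value
  exactly, by the exposure–outcome symmetry of the odds ratio. Estimated ORs
  therefore converge on known truth, which is what the parameter-recovery
  tests assert (planted values must fall inside the 95% CI in ≥90% of seeds).

* **Scale-invariant geometry.** The state side length defaults to
  `sqrt(60 × n_tracts_per_state)` and the road-grid spacing to a twelfth of
  that, so tract and clinic densities per unit area — and hence the fraction
  of tracts that lose their last in-range clinic — are stable whether a
  scenario has 150 tracts or 20,000.

Defaults (`scenario_config()`) encode the study conditions: 20 states (40%
protective), 60 tracts per state, clinic density 0.06 per tract,
affiliation-dependent exit probabilities, a 30-minute threshold, and annual
clinic counts 2006–2020 with a planted slope break at 2019 (−68.2/year
before, −918.8/year after, Gaussian noise).

## A run

```{r}
cfg <- scenario_config(seed = 42)
bundle <- generate_scenario(cfg)
bundle

d18 <- deduplicate_roster(bundle$clinics_2018)$roster
d20 <- deduplicate_roster(bundle$clinics_2020)$roster
records <- classify_access(bundle$tracts, d18, d20,
                           bundle$road_network, bundle$state_laws)
youth_at_risk(records)$by_category

segmented_regression(bundle$annual_counts, breakpoint_year = 2019)
```

`run_pipeline()` wraps all stages and writes every intermediate table (CSV),
a GeoJSON access map, and a run log to an output directory;
`inst/cli/run_pipeline.R` exposes it as a command-line tool.

## Numerical conventions and limitations

* Percentages shown to one decimal use round-half-up (`round_half_up()`),
  matching how administrative reports round, rather than R's default
  round-half-to-even.
* Wald intervals require all four cells positive; predictors with an empty
  cell are skipped (and named) rather than continuity-corrected.
* The drive-time engine is a graph abstraction of a commercial isochrone
  service: no turn restrictions, congestion, or one-way streets. Since both
  epochs use the same network, classification *changes* are driven by roster
  changes only, which is the quantity of interest.
* Medicaid 15–17 estimates inherit the uncertainty of the proportion-based
  allocation; they are bounded above by the tract's 15–17 population.
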