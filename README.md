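# nectartherm

Thermal response of floral nectar secretion and flower production.

## The problem

Floral nectar is the main currency of plant–pollinator interactions, and
its secretion is temperature-sensitive: per-flower nectar volume, sugar
content and daily flower production typically rise to a thermal optimum and
fall off at higher temperatures. In climate-chamber experiments a plant is
walked up a staircase of day temperatures (one step every 3 days, night
held 6 °C below day), three fresh flowers are sampled per plant per step,
and the new flowers opened in the previous 24 h are counted. The question
for Mediterranean species: how do the optima of species flowering in winter
and early spring (early-flowering) compare with those flowering in late
spring and summer (late-flowering), and will projected end-of-century
warming push the ambient temperature past them?

`nectartherm` implements that analysis end to end, for anyone running (or
simulating) stepped-temperature nectar experiments:

1. **Trait derivation** — per-flower sugar mass `v × (c/100) × d(c)` (with
   `d(c)` a quadratic fit of the standard sucrose density table),
   within-plant-day imputation of unreadable concentrations, and plant-day
   aggregation into the five analysis traits (nectar volume per flower,
   sugar concentration, sugar content per flower and per plant, flower
   number).
2. **Mixed models** — per-species quadratic temperature responses
   `y = β₀ + β₁T + β₂T² + b_plant + ε` fitted by REML (`lme4`) on
   log/logit-transformed, standardized scales; time × treatment-group
   control validation models; temperature × flowering-group interaction
   models; ML/AIC comparison of linear vs quadratic trends; Nakagawa
   R²m/R²c.
3. **Thermal optima** — the vertex optimum `T_opt = −β₁/(2β₂)` mapped back
   to °C, and the *5 %-band optimal temperature range*: the interval where
   the fitted curve stays within 5 % of the observed trait range below its
   maximum, solved in closed form as `x* ± sqrt(δ/|β₂|)`.
4. **Climate comparison** — paired t-tests of group optima against
   flowering-month baselines (1958–2001 Aegean means) and seasonal IPCC
   warming increments (RCP4.5 winter/summer, A1B spring).
5. **Empty flowers** — a zero-inflated negative-binomial model of the
   count of nectarless flowers among those sampled, with a log-link mean
   quadratic in temperature.
6. **Synthetic data** — a seeded generator emulating the chamber design
   (plants × steps × 3 flowers, negative-binomial flower counts,
   zero-inflation away from the optimum), so every stage is testable with
   no external data.

## Worked example

```r
library(nectartherm)

prof <- default_species_profiles()$B_acetabulosa   # true optimum 25.9 degC
des  <- species_designs()$B_acetabulosa            # 15 plants, 20-41 degC days

sim <- generate_experiment(prof, des, seed = 42)
pd  <- aggregate_plant_day(impute_concentration(sim$flowers), sim$counts)
fit <- fit_quadratic_lmm(pd, "volume")
optimal_range(fit)
```

prints (output from this code):

```
B_acetabulosa / volume: T_opt 26.5 degC (22.6-30.5), unimodal_concave
```

i.e. the fitted log-volume parabola peaks at 26.5 °C (0.6 °C from the
generating optimum at this seed) and stays within the 5 %-band between
22.6 and 30.5 °C. The full pipeline — six species, optima table, climate
comparison and empty-flower model, written as CSVs plus a manifest:

```r
res <- run_pipeline(pipeline_config(outdir = "out", seed = 11))
head(res$climate)
```

```
             trait    level group n df           t         p annotation
1           volume baseline early 3  2  1.32646714 0.3158827         ns
2           volume baseline  late 3  2  1.44450758 0.2854401         ns
3           volume      p75 early 3  2  0.01598619 0.9886968         ns
...
```

A command-line wrapper with the same stages lives at
`inst/cli/nectartherm.R`
(`Rscript inst/cli/nectartherm.R --stage all --seed 11 --outdir out`).

## Scope notes

The original study's raw measurements were never deposited, so its model
coefficient tables are *not* reproducible from data; they are covered by
property-based tests on the synthetic world instead. The published optima
table and climate figures, which are printed in full, reproduce exactly
(see `reference_optima()`, `climate_scenario()` and the acceptance tests).
The "50 % projection" comparison rows require median warming increments
that were never published; the package refuses to invent them
(`scenario_temperature(month, "p50", ...)` errors unless p50 increments
are supplied explicitly). See `vignettes/thermal-optima-methods.Rmd` for
the full methods account and design decisions.
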