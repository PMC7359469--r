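# empdiseq

Empathy has two partly independent components: **cognitive empathy (CE)**,
recognizing what another person feels, and **emotional empathy (EE)**,
responding to it with an appropriate emotion of one's own. Most studies
relate each component separately to autism traits; `empdiseq` instead
quantifies their *within-person imbalance* — **empathic disequilibrium**,

```
ED = z(CE) − z(EE),        ED-magnitude = |ED|
```

where z(·) is sample standardization, so one ED unit is one standard
deviation of difference between the components. Positive ED means
CE-dominance, negative ED means EE-dominance, and participants can be cut
into **CE-dominant (ED ≥ τ)**, **balanced**, and **EE-dominant (ED ≤ −τ)**
groups (τ = 1 by default, boundaries inclusive).

The package is written for researchers analyzing self-report empathy and
autism-trait batteries (IRI, EQ, AQ, TAS-20, SQ) in general-population
cohorts. It covers the whole workflow:

* **Scoring** — item-level scoring of all five instruments with editable
  YAML keys (`score_instrument()`, `score_battery()`, `default_key()`),
  or direct intake of pre-computed subscale scores; the study exclusion
  rule for extreme low-empathy responders (`apply_exclusions()`).
* **Disequilibrium** — `ed_profile()`, `assign_groups()`, the
  combined-instrument variant `combine_ed()` and the cross-instrument
  concordant subset `concordant_subset()`.
* **Inference** — standardized OLS of autism traits on ED-magnitude
  controlling for total empathy (or CE and EE), sex and age
  (`regress_aq()`); sex-adjusted one-way ANCOVAs across dominance groups
  (`group_anova()`); dominance-vs-balanced planned contrasts with partial
  eta-squared (`group_contrast()`, ηp² = t²/(t²+df)); Bonferroni
  family-wise plans (`multiple_testing_plan()`, `follow_up_plan()`);
  chi-square goodness-of-fit tests of each group's sex composition
  against the whole-sample share (`sex_gof()`); all orchestrated by
  `run_full_battery()`.
* **Simulation** — a calibrated multivariate-normal cohort generator
  (`simulation_config()`, `generate_cohort()`, `generate_item_level()`)
  reproducing the published marginal moments and correlation structure of
  a 671-participant reference cohort, with configurable effect injection,
  so the entire pipeline is testable without access to raw data.

A thin command-line wrapper ships at `inst/cli/empdiseq.R`
(verbs `score`, `ed`, `analyze`, `simulate`, `all`).

## Worked example

```r
library(empdiseq)

cfg     <- simulation_config(n = 671, seed = 2026)  # calibrated defaults
cohort  <- generate_cohort(cfg)
excl    <- apply_exclusions(cohort, "iri", threshold = 4)
battery <- run_full_battery(excl$retained, "iri")
battery
```

```
== Empathic disequilibrium analysis: IRI track (n = 671) ==
-- Dominance groups (tau = 1, raw basis) --
  EE-dominant  n = 124 (m =  45, f =  79)  total  92.49 +/- 11.83  age 23.77 +/- 2.44
  balanced     n = 419 (m = 176, f = 243)  total  94.80 +/- 11.10  age 24.59 +/- 2.49
  CE-dominant  n = 128 (m =  67, f =  61)  total  94.65 +/- 11.99  age 24.39 +/- 2.14
-- Standardized regressions predicting AQ --
  spec 'total' (n = 671, R2 = 0.021):
    ed_magnitude   beta =  0.128  se = 0.038  p = 0.000881
    empathy_total  beta =  0.068  se = 0.038  p = 0.079
    ...
```

The simulated dominance groups are about 19% of the cohort on each side —
the closed-form normal tail for τ = 1 with a CE–EE correlation of 0.365 —
and the regression recovers the injected standardized ED-magnitude effect
(true β = 0.12, here 0.128 ± 0.038): ED-magnitude predicts autism traits
while the total empathy score does not, the pattern the statistic is
designed to isolate.

Desk-level checks reproduce published statistics directly:

```r
sex_gof(65, 47, 0.56)
#> Sex GOF: observed m = 65, f = 47 vs 56% female: chi-square(1) = 8.95, p = 0.00277
etap2_from_t(4.86, 619)
#> [1] 0.03675518
```

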