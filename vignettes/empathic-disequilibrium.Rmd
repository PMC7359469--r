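---
title: "Empathic disequilibrium: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empathic disequilibrium: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(empdiseq)
```

## The statistic

Cognitive empathy (CE) and emotional empathy (EE) are measured on
incommensurable raw scales — within one instrument the subscales differ in
item counts and response anchors, and across instruments (IRI vs EQ) the
scales share nothing at all. Empathic disequilibrium therefore compares the
two components only after sample standardization:

$$\mathrm{ED}_i = z(\mathrm{CE}_i) - z(\mathrm{EE}_i), \qquad
  |\mathrm{ED}_i| = \text{ED-magnitude},$$

with $z(x) = (x - \bar x)/s_x$ using the sample SD (denominator $n-1$).
One ED unit is one standard deviation of difference; the sign encodes the
direction of dominance. Standardization makes ED invariant to any positive
affine rescaling of either raw subscale (re-anchoring a 1–5 scale to 0–4
changes nothing), which the test suite asserts as a property.

Two consequences of the construction are worth keeping in mind:

* Over the analysis sample, $\bar{z(\mathrm{CE})} = \bar{z(\mathrm{EE})} =
  \overline{\mathrm{ED}} = 0$, so "dominance" is always *relative to this
  cohort*, not an absolute trait level.
* $\mathrm{SD}(\mathrm{ED}) = \sqrt{2(1-r)}$, where $r$ is the CE–EE
  correlation. With positively correlated components ($r \approx 0.37$ for
  the IRI, $0.43$ for the EQ), this is about $1.13$ and $1.07$ — *below*
  $\sqrt 2$ but above 1.

## Dominance groups

`assign_groups()` partitions ED at a threshold $\tau$ (default 1):
CE-dominant iff $\mathrm{ED} \ge \tau$, EE-dominant iff
$\mathrm{ED} \le -\tau$, balanced strictly between. Boundary ties go to the
dominance groups; the three groups partition the real line exhaustively.

The phrase "1 SD" is genuinely ambiguous here: it can mean one raw ED unit
(one SD of *difference*) or one SD of the cohort's ED *distribution*
(which is $\sqrt{2(1-r)}$, so a slightly larger cut). Reported group sizes
do not cleanly discriminate between the readings. The package defaults to
raw ED units — the reading under which "a score of 1 represents one
standard deviation difference" is literally true — and offers the
alternative through `grouping_scheme(basis = "ed_sd")`. Under the default,
the closed-form expectation for each dominance tail is
$1 - \Phi\!\left(\tau / \sqrt{2(1-r)}\right)$, about 19% per side at
$r = 0.365$; the simulated cohort reproduces this within Monte-Carlo
error.

## Scoring and keys

Item-level keys (subscale membership, reverse-keyed items, the
response-to-points map) are instrument documentation, not analysis inputs:
every downstream statistic accepts pre-computed subscale scores. The
shipped YAML keys follow the instruments' published scoring conventions —
IRI 28 items, four 7-item subscales, points equal to the 1–5 response
(reverse-keyed mirrored); EQ and SQ 60 items with 40 scored 2/1/0 and 20
fillers; AQ 50 items scored binary toward the autism-keyed side; TAS-20
twenty items on 1–5 with five reverse-keyed. Labs using different
validated keys can edit the YAML (`read_instrument_key()`) or skip item
scoring entirely.

Missing responses follow a "complete instrument required" default: a
participant with any missing item on an instrument receives `NA` scores
there and drops out of the analyses that use it — per-instrument analysis
*n*s may therefore differ, and standardization is always done within the
per-instrument analysis sample after exclusions. Per-subscale mean
imputation is available behind `missing = "impute"`.

The exclusion rule removes participants whose standardized CE **and** EE
both fall below $-4$ SD (z-scores computed on the pre-exclusion sample).
The conjunction reading was chosen because the rule targets participants
implausibly low on *both* components (straight-lining at the scale floor);
a disjunctive variant is available via `rule = "either"`.

## The inference battery

All analyses control for sex (coded male = 0, female = 1 before
standardization; configurable by recoding the column) and, in the
regressions, age.

* **Regressions** (`regress_aq()`): OLS on z-scored outcome and
  predictors, so coefficients are standardized $\beta$. Two rosters:
  ED-magnitude + total empathy, and ED-magnitude + CE + EE. Rank
  deficiency raises a collinearity error naming the offending columns;
  zero-variance predictors raise a degenerate-input error.
* **Omnibus ANCOVAs** (`group_anova()`): the sex-adjusted group effect
  from comparing `outcome ~ sex` with `outcome ~ sex + group`
  ($df_1 = 2$, $df_2 = n - 4$), with
  $\eta_p^2 = F \, df_1 / (F \, df_1 + df_2)$. The omnibus family over
  AQ, TAS-20 and SQ uses a Bonferroni threshold of $0.05/3 \approx 0.017$.
* **Planned contrasts** (`group_contrast()`): each dominance group against
  balanced, taken as the dummy coefficient of the full three-group
  sex-adjusted linear model — i.e. the estimated marginal (sex-adjusted)
  group-mean difference with model residual df — with
  $\eta_p^2 = t^2/(t^2 + df)$. The model never states its contrast
  machinery more precisely than "estimated marginal means"; this contract
  reproduces that workflow exactly (the tests cross-check against
  `emmeans`).
* **Follow-up thresholds**: with $k$ omnibus-significant outcomes and two
  contrasts each, the strict Bonferroni cut is $0.05/2k$. The conventional
  rounded values $0.01$ (for $k = 3$; strict $0.0083$) and $0.0125$
  ($k = 2$) are carried alongside and used for flagging by default;
  `follow_up_plan(use = "strict")` switches to the exact cut. Both values
  appear in every report.
* **Sex goodness-of-fit** (`sex_gof()`): Pearson $\chi^2$ on the two sex
  cells of each group against expected counts from a reference female
  share (by default the analyzed cohort's own share), df = 1, no
  continuity correction, two-sided p-values throughout.

A note on degrees of freedom: with $n$ analyzed participants the contrast
df is $n - 4$. Published analyses of this design sometimes report slightly
smaller df (additional item-level missingness in the raw data); the
package always reports its own df, computed from the rows actually
entering the model.

## The synthetic cohort

`generate_cohort()` draws latent traits
$\{\mathrm{IRI\text{-}CE}, \mathrm{IRI\text{-}EE}, \mathrm{EQ\text{-}CE},
\mathrm{EQ\text{-}EE}, \mathrm{EQ\text{-}rest}, \mathrm{AQ},
\mathrm{TAS\text{-}20}, \mathrm{SQ}, \mathrm{age}\}$ from a multivariate
normal. Defaults encode the reference cohort the package is tested
against: $n = 671$, 56% female, age $24.5 \pm 2.5$ truncated at 18,
AQ $19.19 \pm 4.44$, TAS-20 $41.67 \pm 11.91$, SQ $27.9 \pm 11.05$,
EQ-CE $11.8 \pm 4.06$, EQ-EE $12.59 \pm 4.53$, and composite totals
IRI $94.46 \pm 11.47$, EQ $43.07 \pm 10.41$.

Three calibration constants are not published anywhere and were fixed
once, as modeling choices:

* The within-instrument correlation between subscales forming one
  composite is taken as 0.3 (a typical value for subscales of one
  construct); it only sets the IRI-CE/EE latent SDs, which are then
  rescaled so the IRI *total* SD matches its target exactly.
* EQ-rest — the 18 scored EQ items outside the CE/emotional-reactivity
  factors — gets its SD from solving the EQ-total variance identity, and
  correlates 0.3 with both factors.
* The sex→ED shift defaults to 0.5 SD (male minus female, split around
  the share-weighted mean so component means are unchanged). Under the
  closed-form mixture this yields roughly 60% males among the CE-dominant
  and 70% females among the EE-dominant, qualitatively matching reported
  group compositions. This is calibration, not inference: true
  sex-specific ED distributions are unknown.

Measure-level correlation targets (the published measure-by-measure
matrix plus the within-instrument CE–EE correlations 0.365/0.43) are
propagated to the component level by the exact composite-covariance
identity — a constant component-pair correlation
$r \cdot \mathrm{sd}(M_1)\mathrm{sd}(M_2) / (\sum s_{1i} \sum s_{2j})$
makes the composites correlate exactly $r$ — with unspecified cells left
at 0 and the result projected to the nearest positive semi-definite
correlation matrix by eigenvalue clipping (`nearest_psd_correlation()`;
the maximum perturbation is recorded in the ground-truth ledger and is 0
under the defaults).

Effects are injected on the standardized scale so configured values are
directly comparable to standardized regression coefficients: with
injected $\beta$ the AQ latent becomes
$\sqrt{1-\beta^2}\, z(\mathrm{AQ}) + \beta\, z(|\mathrm{ED}|)$. Because
$|\mathrm{ED}|$ is uncorrelated with every jointly normal latent
(for symmetric $D$, $E[X\,|D|] = 0$ whenever $E[XD]$ exists and $D$ is
centered), the injected value is also the population partial coefficient,
and `regress_aq()` recovers it without attenuation. The default
$\beta = 0.12$ matches the magnitude the statistic is reported to carry;
simulation tests that need a global null set all effects to 0 explicitly.

Scores are continuous by default (analyses use sums of many items, which
are approximately continuous); `discretize = "rounded"` rounds and clips
to instrument ranges for exercising the scoring module, and
`generate_item_level()` expands scores into integer item responses that
round-trip through `score_instrument()` exactly.

**What the simulator does not emulate.** Multivariate normality (real
questionnaire sums are bounded, skewed and heaped), item-level response
styles (acquiescence, straight-lining), measurement non-invariance across
sex, any nonlinear CE–EE dependence, and missingness mechanisms (the
generator produces complete cases). Passing calibration and recovery
tests therefore shows the *pipeline* is correct under its own model, not
that the model captures every feature of real cohorts.

## Numerical choices and degenerate inputs

* Standardization requires $n \ge 2$ non-missing values and nonzero
  variance; violations raise classed errors
  (`empdiseq_structural_error`, `empdiseq_degenerate_error`) rather than
  propagating `NaN`.
* `compute_ed()` refuses non-finite inputs; incomplete participants are
  dropped (and logged) before it runs.
* Boundary ties at exactly $\pm\tau$ go to the dominance groups.
* The PSD repair floors eigenvalues at $10^{-8}$ and rescales to unit
  diagonal; the perturbation is reported, never silent.
* Item-level expansion distributes a subscale score greedily across items
  within per-item point ranges; unattainable scores are clipped with a
  warning.
* All simulation randomness flows from a single integer seed;
  `generate_cohort()` is bit-for-bit reproducible given (config, seed).

## Problem sizes used by the test suite

Calibration fidelity is checked on one cohort of $n = 20{,}000$ (every
configured mean, SD and correlation within 3 Monte-Carlo SEs); parameter
recovery on 200 replicates of $n = 5{,}000$ (estimate within 3 SEs of the
injected 0.12 in at least 90% of replicates); familywise type-I control
on 500 null replicates of $n = 600$ (rate at most the nominal 0.05 plus
binomial error). These sizes give Monte-Carlo error comfortably below the
tolerances they are tested against while keeping the default suite fast.

## Known limitations

* ED is a descriptive statistic plus labels; nothing here supports causal
  claims about empathy imbalance and autism traits.
* Difference scores inherit the reliabilities of their components; with
  component correlation $r$, the reliability of ED is below that of
  either component. The package does not estimate reliability
  (psychometric validation is out of scope).
* Group membership is cohort-relative (standardization) and
  threshold-dependent; comparisons of group *sizes* across studies are
  only meaningful under the same basis and τ.
* The shipped instrument keys follow published conventions but item-level
  key identity cannot be verified from summary statistics alone; use
  pre-scored input when your lab's keys differ.
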