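---
title: "Methods: sandwich-substitution modeling, HEI-2010 scoring and survey estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sandwich-substitution modeling, HEI-2010 scoring and survey estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietshift)
```

This vignette is the package's account of its own methods: the model each
module implements, the assumptions behind it, the parameters that matter,
and the places where the design was genuinely open and a choice had to be
made.

## The modeling question

Item-level 24-hour recall data record what each surveyed person ate on one
day, with survey design information (stratum, primary sampling unit,
weight) that makes weighted summaries nationally representative. The
package models a *substitution counterfactual*: remove the energy,
nutrients and food-pattern equivalents contributed by the sandwiches
people actually reported, inject a prespecified composite sandwich in
their place, and re-estimate population means and diet quality. The
modeling is deliberately theoretical — a formulation exercise that shows
how sandwich composition drives daily intake, not a behavioural
prediction. Condiments are not modeled, only Day-1 recalls are used, and
dietary supplements are excluded throughout so results reflect foods and
beverages only.

## Composite construction

A composite is specified by food-group targets
(`composite_spec()`), e.g. 2 oz eq of whole grains, 2.5 oz eq of meat,
1 cup eq of cheese, 0.1 cup eq each of dark-green and red/orange
vegetables. For each targeted group, the qualifying food codes are blended
by **proportional consumption weighting** (`consumption_weights()`): the
weight of code $f$ is its share of the survey-weighted gram total,

$$w_f = \frac{\sum_{d} W_d\, g_{d,f}}{\sum_{d}\sum_{f'} W_d\, g_{d,f'}},$$

with $W_d$ the person-day weight and $g_{d,f}$ grams of $f$ consumed.
Food $f$ then contributes $T_g w_f$ equivalents, realised as
$T_g w_f / d_f$ grams through its equivalent density $d_f$
(equivalents per gram); nutrients accumulate gram-proportionally, and the
targeted groups land exactly on their targets (to floating point) whenever
foods carry only the group they qualify for.

Open choices, decided as follows:

* *What "as eaten" weighting means.* Survey-weight × grams was chosen over
  unweighted eating frequency or equivalent shares, because grams consumed
  under the survey weights is what makes the blend population-
  representative. Zero-consumption codes are dropped (weight 0), not given
  uniform mass.
* *Foods qualifying for two groups* are weighted independently within each
  group; the groups are treated one at a time.
* The five shipped profiles are a fixture rather than rebuilt at load
  time: rebuilding would require the full national food-composition and
  pattern-equivalent databases, which the package deliberately does not
  bundle. `build_composite()` is exercised on toy databases in the tests.

## The packaged profiles

`load_builtin_profiles()` returns the control ("Sandwich 0", the sandwich
as currently consumed) and five modeled sandwiches. Their nutrient
vectors are packaged exactly as published. Three fields need care:

* **Added sugar** is not printed in the profile table; it is stored as 0
  for all six profiles. Substitution deltas for added sugar are therefore
  driven by the recall data, not the profiles.
* **Food-pattern equivalents** of the modeled sandwiches are only
  partially published: the composite targets (grains, meat, dairy,
  vegetables) are known; fatty-acid grams, solid-fat energy and added
  sugar teaspoon equivalents are not, and the taco's groups are not stated
  at all. The package ships constructed values for these in a file
  labelled `_synthetic` (e.g. the unsaturated remainder of total fat split
  65/35 MUFA/PUFA, solid fat sized to cheese-and-meat profiles, corn
  tortillas counted as whole grain at 1 oz eq). They matter only when
  scoring modeled days with the HEI, and are documented as assumptions.
* **The control's groups are unknown** (`groups_known = FALSE`, all-zero
  vector). Pipelines score scenario 0 from the recall data's own
  item-level group fields; the control profile never injects groups.

## The substitution engine

`identify_sandwiches()` flags items by WWEIA category or food code. The
shipped default list (burgers, frankfurter, poultry, egg and other
sandwiches) is editable configuration: the source survey's exact category
list is not published, so no fidelity is claimed. `substitute_day()` then
computes

$$\text{modified} = \text{baseline} - \sum_{\text{flagged}} x_i + k\cdot
\text{profile},$$

with $k$ the number of flagged occurrences. Two open choices:

* *Granularity.* Each flagged occurrence is replaced by one **fixed-size**
  composite, not scaled by the replaced item's grams: the composites are
  defined as prespecified amounts, so portion scaling would change their
  definition. A consumer-day granularity (replace all of a day's
  sandwiches with one composite) was rejected for the same reason.
* *Totals, not items.* Replacement happens at the daily-totals level; item
  lists are never rewritten, because the downstream analysis consumes only
  totals.

Negative modified totals cannot arise from consistent inputs (the flagged
items are part of the baseline sum); as defence against inconsistent
hand-built inputs they are clamped to zero with a warning. Tiny
floating-point violations of the food-group hierarchy
(whole ≤ total fruit, etc.) after removal are repaired by nudging the
parent up to its child.

## HEI-2010 scoring

Diet quality is the Healthy Eating Index 2010: twelve components, 100
points. Nine adequacy components score densities per 1000 kcal (total and
whole fruit, total vegetables, greens and beans, whole grains, dairy,
total protein, seafood/plant protein) or the fatty-acid ratio
(MUFA+PUFA)/SFA; three moderation components (refined grains, sodium in
g/1000 kcal, empty calories as % of energy) score downward. Every
component is a clipped linear ramp between its zero-score and full-score
standards (`hei_standards()` exports the table as a CSV resource).
Conventions:

* Empty calories count solid fats, added sugars at 16 kcal per teaspoon
  equivalent, and alcohol at 7 kcal/g beyond 13 g per 1000 kcal.
* Zero-energy days score 0 on every component (no division by zero).
* Fatty-acid ratio with SFA = 0: maximum points if unsaturates are
  present, else 0.
* Scoring is **person-level**: each person-day is scored and the scores
  are survey-averaged, matching a least-square-means presentation of
  scores. The population-ratio method (score the weighted mean intake) is
  intentionally not implemented.

Every density is invariant under proportional rescaling of a day's
amounts and energy, which the property tests exercise.

## Survey estimation

The survey module treats "least square means" as covariate-free
survey-weighted means — the named means procedure estimates means, not a
regression — so no covariate adjustment is performed. The mean is the
ratio estimator $\hat{y} = \sum w y / \sum w$; its variance is the
first-stage with-replacement Taylor linearization: with
$z_{hij} = w_{hij}(y_{hij} - \hat{y})$ summed to PSU totals $z_{hi}$,

$$\widehat{\mathrm{Var}}(\hat y)=\frac{1}{(\sum w)^2}\sum_h
\frac{n_h}{n_h-1}\sum_i (z_{hi}-\bar z_h)^2,$$

with $df = \#\text{PSU} - \#\text{strata}$ and two-sided $t$ limits
(99% by default, matching the LCL99/UCL99 decision rule). Strata with a
single PSU are a hard error by default; an opt-in collapse rule merges
them into the adjacent stratum for real-data robustness. Two estimates
differ *meaningfully* iff their closed intervals are disjoint — a shared
endpoint is overlap. Non-overlap of two 99% intervals is a conservative
rule: it flags fewer contrasts than a formal test of the difference at
the 1% level, which is the intended reading of the published decision
rule.

## The synthetic-data generator

`gen_population()` emulates exactly the structure the estimators assume,
with known ground truth:

* 14 strata, two PSUs per stratum (participants cycle deterministically
  through strata and PSUs so no stratum is left with a single PSU),
  log-normal weights (sdlog 0.6) — the shape of a national survey design
  at reduced scale.
* Background daily intake per person-day drawn as truncated normals
  (sd = 40% of the mean) and split over ~Poisson(10) items; the means are
  sized so that background plus 0.78 typical sandwiches lands at US-adult
  daily totals (≈2300 kcal, ≈3860 mg sodium, HEI ≈ 49).
* Sandwich occurrences are Poisson(0.78) per person-day — with ~54% of
  days containing at least one sandwich, echoing the near-half of US
  adults who eat one on any given day — and each sandwich item is the
  configured profile times a mean-one log-normal multiplier (CV 0.15).
  The control profile's unknown equivalents are filled with constructed
  refined-grain/meat/cheese values for generation.
* `expected_scenario_shift()` supplies the analytic expectation
  $r\,(\text{profile}_{out}-\text{profile}_{in})$ against which the full
  pipeline is checked (recovery within 3 estimated SEs per nutrient).

What the generator does **not** emulate: real recall data's skewed and
zero-inflated nutrient distributions, demographic covariates, intra-person
day-to-day correlation, differential reporting error, or any correlation
between sandwich consumption and the rest of the diet. Passing tests
therefore demonstrate the correctness of the *pipeline arithmetic and the
estimators under the stated design*, not fidelity to any particular
survey's empirical distributions.

## Numerical choices and problem sizes

* Group-closure and conservation checks use absolute tolerances of 1e-9;
  component-score oracle agreement 1e-12.
* The test and acceptance runs use populations of 1,000–2,000 person-days,
  1,000 random designs for the variance oracle, 1,000 replicates for
  CI coverage, and ~10,000 random values for the HEI ramp oracle — sizes
  at which every stochastic check has comfortable resolution while the
  whole suite stays quick on a single CPU.
* Displayed tables round means ≥ 100 to integers and smaller means to one
  decimal with three-significant-digit SEs; CSV outputs always carry full
  precision.

## Known limitations

* The composite builder assumes single-group qualifying foods for exact
  target closure; multi-group foods close their own group but spill their
  secondary groups into the profile (documented, intentional).
* The shipped WWEIA sandwich-category list and the synthetic group fields
  of the packaged profiles are assumptions, editable by the user.
* No replicate-weight (BRR/jackknife) variance, no domain estimation, no
  HEI-2015/2020.
* SAS transport files are read-only, and that code path is exercised only
  for dispatch (no XPT writer exists in the package's dependency set to
  round-trip against); CSV is the canonical interchange format.
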