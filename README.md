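# dietshift

Sandwich-substitution modeling of nutrient intake and diet quality in
24-hour dietary recall surveys.

Sandwiches are a mainstay of the US adult diet, and the ones actually
eaten — burgers, cold cuts, hot dogs — are dense in energy, saturated fat
and sodium. `dietshift` asks the counterfactual question a nutrition
modeler asks of recall data: *what would population intake and diet
quality look like if every reported sandwich were replaced by a
prespecified, healthier composite sandwich?* The package is aimed at
nutritional epidemiologists working with NHANES/WWEIA-style item-level
recall data, and at anyone who needs the pieces — composite construction,
HEI-2010 scoring, stratified survey estimation — on their own.

## What it does

1. **Composite construction.** A composite sandwich is defined by
   food-group targets (e.g. 2 oz eq whole grains, 2.5 oz eq meat, 1 cup eq
   cheese, 0.1 cup dark-green + 0.1 cup red/orange vegetables). Qualifying
   food codes are blended by *proportional consumption weighting*: code
   *f* gets weight
   `w_f = Σ_days weight·grams_f / Σ_days Σ_f' weight·grams_f'`,
   and contributes `T_g · w_f` equivalents of its group, i.e.
   `T_g · w_f / d_f` grams where `d_f` is its equivalents-per-gram
   density. Six profiles ship built in (`load_builtin_profiles()`):
   the typical sandwich as consumed (control) and five modeled ones.
2. **Substitution.** Items whose WWEIA category (or food code) is in the
   editable sandwich list are flagged; each flagged occurrence is removed
   from the person-day's totals and one fixed-size composite is injected:
   `modified = baseline − Σ flagged + k · profile`. No portion scaling —
   composites are prespecified amounts.
3. **Diet quality.** HEI-2010: 12 components, 100 points, densities per
   1000 kcal (sodium in g/1000 kcal, fatty acids as (MUFA+PUFA)/SFA,
   empty calories as % of energy from solid fats, added sugars at
   16 kcal/tsp eq, and alcohol beyond 13 g/1000 kcal at 7 kcal/g), each
   scored by a clipped linear ramp between its standards.
4. **Survey estimation.** Weighted means with Taylor-linearized variance
   for stratified cluster designs:
   `Var = Σ_h n_h/(n_h−1) Σ_i (z_hi − z̄_h)² / (Σw)²` with
   `z = w(y − ŷ)` summed to PSU totals, `df = #PSU − #strata`, t-based
   99% limits. Two scenarios differ *meaningfully* when their 99% CIs do
   not overlap (closed intervals; touching endpoints overlap).
5. **Synthetic populations.** `gen_population()` emulates the survey
   structure (strata, two PSUs each, log-normal weights, background items,
   Poisson sandwich occurrences with mean-one noise) with known ground
   truth, so the whole pipeline is testable offline;
   `expected_scenario_shift()` gives the analytic population shift
   `rate · (profile_out − profile_in)`.

## Worked example

The analysis workflow lives in `analysis/` (simulate → substitute →
estimate), each a thin driver over package functions:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_substitute.R
Rscript analysis/03_estimate.R
```

On the default synthetic population (2,000 person-days, seed 2025,
0.78 expected sandwiches/day) this prints, among other things:

```
 measure scenario     mean_se       ci99
  energy        0 2313 ± 20.7 2251, 2375
  energy        5 2072 ± 18.7 2016, 2128

       measure scenario      mean_se       ci99
 hei2010_total        0 49.1 ± 0.238 48.4, 49.8
 hei2010_total        5 55.0 ± 0.224 54.4, 55.7

Scenarios meaningfully different from the control in energy: 3, 5
```

Reading: under the control scenario (0) the population's mean daily
energy is 2313 kcal; swapping every typical sandwich for the soft corn
tortilla taco (scenario 5) drops it to 2072 kcal — a ~240 kcal/day
reduction whose 99% CI does not overlap the control's, so the change is
deemed meaningful — and raises the mean HEI-2010 diet-quality score from
49.1 to 55.0 out of 100. Full-precision tables land in `results/tables/`,
pairwise non-overlap matrices in `results/meaningful/`.

The same pipeline runs on real item-level recall CSVs (or NHANES `.XPT`
files) via `read_recall_table()` + `run_config(data = ...)`; see
`?read_recall_table` for the column dictionary.

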