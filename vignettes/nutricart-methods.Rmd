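---
title: "Methods: label engines, basket scoring and the crossover analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label engines, basket scoring and the crossover analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutricart)
```

`nutricart` evaluates front-of-pack (FOP) nutrition labels on grocery
baskets collected under a three-condition within-person crossover design
(no-label Control, Multiple Traffic Lights, Nutri-Score). This vignette is
the package's own account of the science it implements: the scoring
algorithms and their constants, the statistical model and its assumptions,
the synthetic-data generator, and the numerical conventions that decide
edge cases.

## Nutri-Score grading

`nutriscore_food()` implements the points-based nutrient-profiling food
algorithm. Per 100 g, four *negative* components each contribute 0–10
points (energy in kJ, total sugars, saturated fat, sodium) and three
*positive* components 0–5 points (fruit/vegetable/nut/legume share,
fiber, protein). A value earns one point per band threshold *strictly
exceeded* — a value exactly on a threshold stays in the lower band, the
convention used throughout the package wherever a source is ambiguous,
and the one the unit tests pin down. Protein points are withheld when the
negative total reaches 11 unless the fruit/vegetable component already
scores its maximum of 5. Final points (negative − positive, range −15 to
40) map to grades A ≤ −1, B 0–2, C 3–10, D 11–18, E ≥ 19, and to the
numeric scale A = 5 … E = 1 used for basket averaging. The band constants
are exposed read-only via `ns_point_bands()`; their provenance (the 2017
French implementation of the British FSA/Ofcom model) is recorded beside
the tables in the source. The special-category variants of the scheme
(cheeses, added fats, the 2023 revision) are deliberately out of scope:
this package targets the general-food algorithm as deployed in the trial
setting it models.

Beverages are not graded with the food algorithm — under it the large
majority of drinks collapse into D/E, defeating the label's purpose. The
scheme the package mirrors is a calorie/sugar-focused national adaptation
whose exact rule is proprietary; `nutriscore_beverage()` therefore
implements a *transparent surrogate*: zero sugar is grade A by fiat (the
one publicly stated rule, so it is fixed); otherwise ascending sugar
thresholds (defaults 2.5/4.5/6.5 g per 100 g for B/C/D, E above) with a
one-grade penalty above 60 kcal/100 g. The defaults were fixed once so
the default synthetic beverage assortment lands near the intended
29/11/3/3/54% A–E spread; the published B/C/D shares cannot identify the
proprietary thresholds, so the surrogate targets the distribution, not
the hidden rule, and every threshold is configurable via
`beverage_rules()`.

## Multiple Traffic Lights

`mtl_colors()` colors fat, saturates, sugars and salt per the UK FOP
technical guidance: per-100 g green/amber/red bands (foods: fat 3/17.5 g,
saturates 1.5/5 g, sugars 5/22.5 g, salt 0.3/1.5 g; boundaries inclusive
on the low side) with red forced when a portion larger than 100 g exceeds
the per-portion trigger (21/6/27/1.8 g). Beverage thresholds are the food
bands halved, with the portion trigger applied above 150 g — a single
documented rule in place of the guidance's slightly irregular drink
values. Salt is derived from sodium at the standard 2.5 g salt per
1000 mg sodium. The label's numeric side — per-serving energy and percent
of EU reference intakes — is reported alongside the colors. For the
shopper simulator the four colors are collapsed to a 1–5 score (2 points
per green, 1 per amber, rescaled) so both labels inject "healthiness" on
a comparable scale.

## The modified AHEI-2010

Basket diet quality is a nine-component modification of the Alternative
Healthy Eating Index 2010: vegetables, fruit, whole grains, sugar-sweetened
beverages + fruit juice, nuts and legumes, red/processed meat, trans fat,
long-chain n−3 fats, and sodium, each scored 0 (worst) to 10 (best), for
a maximum of 90. Alcohol (not sold in the store being modeled) and
polyunsaturated fat (absent from nutrition panels) are dropped from the
published 11-component/110-point index. A wrinkle worth recording: the
source trial describes using "eleven of 13" components while stating a
90-point maximum; the two statements are inconsistent, and the package
follows the nine components actually listed together with the stated
maximum of 90. Component anchors are the published ones
(`ahei_anchors()`), with linear interpolation between worst and best and
clamping outside. Two anchors needed decisions:

* **Whole grains.** The published optimum is sex-specific (75 g/day women,
  90 g/day men). Baskets are household-level, so a single default of
  90 g/day is used; it is the more conservative (harder) target and can
  be overridden through the `anchors` argument.
* **Sodium.** The published index scores sodium by cohort decile (lowest
  decile 10, highest 0). The package scores decile rank *d* as
  10·(10−d)/9 against cut-points computed, by default, over all
  person-day sodium values in the analyzed cohort
  (`sodium_decile_cutpoints()`), overridable with fixed cut-points for
  cross-cohort comparability.

Intakes are per-person-per-day: a weekly household order is divided by
the number of adult household members and by seven
(`per_day_per_person()`). "Adult" is whatever the participant table says
— the package takes `n_adults_in_household` as given. Trans fat enters as
percent of energy (9 kcal/g over the basket's total energy); a
zero-energy basket has a zero trans-fat share by convention. Component
intakes come from explicit per-serving catalog annotations
(`ahei_*` columns) rather than free-text product-name inference, because
mapping products to food groups is not derivable from a nutrient panel;
the synthetic generator populates them by archetype. An empty order is
defined as all-zero intakes and scores whatever zeros score — this is
documented behavior, not an error.

The serving-weighted average Nutri-Score is
Σ(servings·value)/Σ(servings) with servings = packs × servings-per-pack.
"Weighted by serving size" is thus read as weighting by the *number of
servings purchased*, not by gram weight — consistent with grading "each
food purchased" — and the choice is isolated in `average_nutriscore()`
should a gram-weighted variant ever be wanted. A basket with zero
servings has no defined average and returns `NA`.

## The first-difference crossover model

Each participant shops once per condition in randomized order; for every
treatment shop with an available control shop the package forms
Δy = y(treatment) − y(control) and fits

Δy_is = α + β_NS·NS_is + ε_is

by OLS (`fit_first_difference()`). Differencing removes all
time-invariant individual heterogeneity, which is the design's central
asset; the model deliberately fits no carryover or period effects.
Participants contribute up to two differences, so errors are clustered by
participant: the covariance is the CR1 sandwich (HC1 finite-sample factor
times G/(G−1)), the common default of applied econometrics software, and
the test suite checks it against a hand-written sandwich. P-values use a
t reference with degrees of freedom = clusters − parameters; both the
correction and the df are arguments. The three reported contrasts are α
(MTL vs Control), β_NS (NS over MTL) and α + β_NS (NS vs Control); the
identity `alpha_plus_beta = alpha + beta_ns` holds to machine precision
by construction. P-values are two-sided by default — matching how such
trials conventionally report — with `sided = "greater"` available for the
directional improvement hypotheses.

Moderator analyses (`fit_moderator()`) interact a binary moderator with
the NS dummy: β_M shifts the MTL effect, β_M + β_int the NS effect.
Hunger and mood are median splits of the post-shop survey, with ties sent
*up* (a value equal to the median codes 1); the treatment shop's survey
values are used (which shop's state should matter is not identified by
the design; the choice is localized in `build_differences()`). Income and
education indicators come from the participant table.

`run_crossover()` repeats the analysis per outcome and optionally
restricted to food or beverage lines. The modified AHEI is excluded from
stratified runs by design — its components span food and drink groups and
are not scored in isolation — and requesting it per stratum is an error
rather than a silently wrong number. Shops emptied by a stratum filter
get missing outcomes and drop out of the differencing.

`sample_size_crossover()` is the paired normal approximation
n = ⌈((z₁₋α/(2k) + z_power)/d)²⌉ with Bonferroni adjustment for k
comparisons. Under d = 0.30, α = 0.05, power = 0.90, k = 3 it returns
151. Trials of this design have quoted ~140 under the same stated
parameters; that figure is not reproduced by this standard formula, the
exact software behind it being unknown, so the package documents the
discrepancy instead of tuning toward it. `implied_cad_reduction()` is the
linear extrapolation (Δ/10)·r of an AHEI gain to a coronary-artery-disease
risk reduction, given a cohort association of r percent per 10 points.

## The synthetic generator

`simulate_trial()` exists so the full pipeline is testable end to end
with known ground truth. What it emulates, and the defaults it freezes:

* **Catalog** (`generate_catalog()`): 4,175 products, 832 of them
  beverages. Foods are drawn from 15 archetypes (vegetables, fruit,
  legumes, nuts, whole and refined grains, plain and dessert dairy, red
  and processed meat, fish, composite meals, sweet and savory snacks,
  condiments) with truncated-normal nutrient distributions; saturated fat
  is generated as a fraction of total fat (so satfat ≤ fat by
  construction) and energy is derived from the macronutrients, keeping
  panels internally consistent. Archetype mixture weights were solved
  once — penalized least squares against the target A–E shares
  (26/12/26/25/9.8% foods, 29/11/3/3/54% beverages) with a
  realistic-assortment prior — and frozen; the defaults land within
  about two percentage points of each target share.
* **Cohort** (`generate_participants()`): 168 recruits; age
  34.69 ± 6.83 years (truncated at the 21-year eligibility floor), BMI
  23.31 ± 4.07, 68.7% female, 67.0% university-educated, 32.7%
  high-income; household adult counts default to 25/50/15/10% for 1–4
  adults (a choice, since the source reports none). Sequences are random
  permuted blocks: each block of six participants receives the six
  orderings of the three conditions exactly once.
* **Shops** (`simulate_shops()`): products are drawn with probability
  ∝ exp(u), u = appeal − θ_price·price + γ_cond·(health − 3), where
  health is the 1–5 Nutri-Score value under NS and the color-derived MTL
  score under MTL, and γ_Control = 0. Items accumulate until the total
  reaches the $50 minimum; prices are capped at $20, so totals always
  land inside the $50–$100 window. Completion follows the observed
  pattern (probabilities 14/168, 7/168, 2/168 of placing 0/1/2 orders,
  the rest completing all three). Defaults γ_MTL = 0.12, γ_NS = 0.15
  were fixed once to produce label effects of the magnitude such trials
  observe (about one AHEI point, a few tenths of a Nutri-Score point) —
  real shoppers admit no "true" γ, so these are honest stand-ins, not
  estimates.
* **Direct-shift mode** (`simulate_differences()`): generates
  first-difference observations directly as effect + participant noise +
  shop noise. It exists because statistical calibration (type-I error,
  parameter recovery) needs truth in outcome units, which utility-scale
  injection cannot supply in closed form; the utility route remains the
  one that exercises the scoring stages.

What the generator does **not** emulate: brand-level prices and
promotions, taste correlations within households, repeat-purchase
loyalty, seasonality, basket composition heuristics (meal planning), or
any behavioral response to the survey. Passing tests therefore show that
the *pipeline* is correct and well-calibrated under a plausible shopping
model — not that any particular real-world effect size is right.

## Numerical conventions and degenerate inputs

* Energy: 4.184 kJ/kcal wherever one unit is derived from the other;
  catalogs carrying both are validated to agree within 2%.
* Spend window: boundaries inclusive, compared at cent precision
  (a $50.00 basket passes, $49.99 fails).
* Band/threshold ties: the lower band wins, everywhere, and is
  unit-tested at the exact boundaries.
* Empty baskets: totals 0, per-serving means and average Nutri-Score
  `NA`, AHEI scored on zero intakes; missing outcomes drop out of
  differencing rather than propagate.
* Rank deficiency (one treatment arm only, constant moderator) and
  sub-minimal inputs raise classed errors, never silent `NA` estimates.
* All generator randomness flows from one integer seed through
  stage-offset seeds, so catalog, cohort and shops are independently
  reproducible and `run_pipeline()` is byte-stable given a config.

## Problem sizes used by the test suite

The suite checks the Nutri-Score engine against an independent band-scan
oracle on 10,000 random panels (with atoms at band boundaries), the
type-I error of the one-sided α test over 2,000 replications of a
150-participant null, parameter recovery at n = 150, and the full
simulate→score→analyze chain at 150 participants × 1,500 products —
sizes chosen to make Monte-Carlo noise small relative to the tolerances
while keeping a full run around a minute.

## Known limitations

The beverage surrogate matches a grade distribution, not the proprietary
rule generating it; AHEI component yields are catalog annotations, so
garbage annotations give garbage scores (the validators only enforce
non-negativity); the analysis offers no mixed-effects or GEE alternative
and no carryover modeling, by design; and the generator's behavioral
model is an artifact device — its γ parameters shape simulated effect
sizes and nothing more.
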