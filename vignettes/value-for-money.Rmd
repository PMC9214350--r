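---
title: "Ranking ECD interventions by value for money: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking ECD interventions by value for money: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecdcea)
```

## The problem

Early childhood development (ECD) interventions — parenting support, home
visiting, psychosocial stimulation — improve continuous outcomes in four
developmental domains (motor, cognitive, language, socioemotional), not
survival or morbidity. Deaths averted and DALYs therefore cannot serve as
the effect unit, and no disability weights exist for developmental
domains. `ecdcea` implements the alternative: express benefit as a
weighted sum of standardized effect sizes and rank interventions by
incremental cost per SD of aggregate developmental gain.

## Model and assumptions

For arm $i$ with per-child cost $C_i$ and reported domain effects
$Z_{d,i}$ (Cohen's $d$, control-relative):

$$\mathrm{ICER}_i \;=\; \frac{C_i - C_0}{\sum_d w_d Z_{d,i} - \sum_d w_d Z_{d,0}}$$

- **Status quo.** Published effects and costs are already incremental to
  each study's own control, so $C_0 = B_0 = 0$ by default; the API accepts
  explicit baselines for general use. No discounting is applied anywhere:
  the time horizon is each study's own, and the framework deliberately
  evaluates immediate developmental impact.
- **Weight schemes.** `averaged` sets $w_d = 1/D$ over the $D$ effects an
  arm reports (mean across reported domains); `summed` sets $w_d = 1$.
  Custom non-negative weight maps express policymaker priorities. Exactly
  one identity links the presets: averaged = summed / $D$ per arm, so the
  two league tables differ only where $D$ differs across arms.
- **Subgroups.** When a study reports the same domain for distinct
  subpopulations (e.g. iron-deficient vs. non-iron-deficient cognitive
  effects), each subgroup estimate is one aggregation component. That is
  the only reading that reproduces the published averaged value of 0.70
  for the arm concerned ($ (1.80 + (-0.41))/2 = 0.695 $).
- **Non-significant effects** are included in aggregation; exclusion of
  arms from ranking is a data flag (`league_eligible`), never a
  significance filter. A reported 0.00 effect legitimately dilutes an
  arm's average.
- **Uncertainty propagation** is bound-wise interval arithmetic: the
  aggregate lower (upper) bound is the weighted sum of component lower
  (upper) bounds, and with cost treated as fixed the effect UR maps
  inversely onto the ICER UR ($\mathrm{ICER}_{lower} = \Delta C / B_{upper}$).
  This is not a variance-based CI; it is the only rule consistent with
  every published interval the package reproduces (e.g. an upper ICER
  bound of \$33,925 = 1357/0.04). Correlation between domain effects is
  ignored by construction — a known limitation, discussed below.
- **Domination.** An arm whose aggregate point effect is $\le 0$ has no
  meaningful ICER; it is flagged `dominated`, excluded from ranking and
  listed separately. When only the aggregate *lower bound* is $\le 0$,
  the point ICER exists but its upper UR bound is unbounded (`Inf`,
  flagged).

## Numerical choices

- **Full-precision intermediates.** Aggregates are never rounded before
  division. This is observable: one three-domain arm's averaged ICER is
  $1290 / (2.35/3) = \$1647$, whereas dividing by the displayed 0.78
  would give \$1654; similarly a lower bound of \$177 requires the
  unrounded 0.755.
- **Display rounding** (`round_display`) shows money to the nearest
  dollar and effects to two decimals, with **ties to even**. The
  convention is recovered from the published tables, which contain two
  exact-half cells that no half-away rule can reconcile:
  $69/0.40 = 172.5$ prints as \$172 while $99/0.40 = 247.5$ prints as
  \$248. Values within a $10^{-6}$ relative tolerance of an exact half
  are snapped to it before rounding, so binary floating-point
  representations of decimal inputs cannot flip a tie.
- **Ranking ties** (equal unrounded ICER) break by lower per-child cost,
  then lexicographic `arm_id`; ranking is therefore a pure function of
  the input set, independent of input order.

## Cost standardization

Ingredients-based costing derives a unit cost per child from itemized
inputs. To compare interventions run in different countries and years,
`standardize_unit_cost()`:

1. inflates **workforce** ingredients to the reference year (default
   2010) with the country's consumer price index,
2. multiplies them by `reference_wage / local_wage(country, 2010)`, with
   the anchor `reference_wage = 3549` US\$/person-year (average 2010 GDP
   per capita across low- and middle-income countries),
3. passes **non-workforce** ingredients (books, toys, materials) through
   unchanged, treating them as already standardized across settings,
4. divides by the number of children targeted.

CPI-first-then-wage-ratio is fixed by convention; both steps are scalar
multiplications, so the order does not affect the result, but fixing it
keeps audits unambiguous. Both tables are configuration inputs (JSON, or
YAML when the `yaml` package is available) — nothing is downloaded at run
time, and the shipped tables (`synthetic_costing_params.json`,
`synthetic_ingredients.csv`) are illustrative synthetic data, not any
statistical agency's series. Which wage series defines `local_wage` for a
given country is a user decision carried in configuration.

The bundled portfolio's standardized per-child costs are shipped as data:
the per-study ingredient breakdowns behind them were never published, so
they cannot be recomputed. The costing module is therefore exercised and
property-tested on synthetic ingredients (linearity, monotonicity,
wage-ratio scaling), not golden-tested.

## The bundled portfolio

`ecd_study_portfolio()` returns 16 arms from 15 published studies of early
parenting and at-home psychosocial stimulation for children under 2 in
LMICs (study years 1991–2012), with effects, 95% URs, significance flags,
local and standardized per-child costs, and study years (flagged where
imputed as publication year − 1). Values are stored exactly as printed,
including one interval whose lower bound equals its point estimate; no
corrections are applied. Twelve arms carry `league_eligible = TRUE`; the
published source does not state the rule that excluded the other four, so
eligibility is data, not a computation. An md5 checksum is verified at
load. `replicate_reference()` recomputes all four league tables and diffs
every display cell — ICER points, both UR bounds, ranks, effect cells and
costs — against the published reference shipped alongside.

```{r}
replicate_reference()
```

## Synthetic portfolios

`generate_portfolio()` emulates the statistical shape of the bundled set:
1–4 reported domains per arm; true effects uniform on $[-0.4, 1.8]$ SD
(the observed range); symmetric 95% URs implied by standard errors uniform
on $[0.07, 0.25]$ SD (the observed half-widths); per-child costs
log-normal with log-mean 5 and log-sd 1.5, matching the observed $1–$3519
span and right skew; and an independent log-normal standardization
multiplier (log-mean $\log 2$, log-sd 0.5) standing in for wage
re-referencing. These defaults were fixed once from the observed data and
are not tuned.

Because generated URs are symmetric, the aggregate point equals the
aggregate of the true effects and the analytically implied ICERs attached
as `ground_truth` are exact — which is what makes rank-recovery a sharp
property test. The generator does **not** emulate: asymmetric or
truncated URs, correlated domain effects within a study, missing total
costs, subgroup splits, or any cost–effect dependence. A green synthetic
test therefore establishes arithmetic and ranking correctness, not
robustness to those real-data features.

## Monte Carlo intervals (extension)

`monte_carlo_interval()` samples each effect independently from
$N(\text{estimate}, (\text{upper} - \text{lower})/3.92)$, aggregates per
draw, and returns empirical 2.5th/97.5th percentiles of cost divided by
the positive aggregates; non-positive draws are counted and reported.
Normality of effects is an assumption the interval-arithmetic pipeline
never makes, so this feature is labelled an extension in its output and
plays no part in the replication checks. A seed is mandatory.

## Known limitations

- Aggregation is additive; correlated or mutually reinforcing domain
  effects within a study are not modelled.
- No meta-analytic pooling: arms are never combined across studies.
- No discounting, no DALY bridge, no willingness-to-pay thresholds or
  acceptability curves; no equity/distributional weighting.
- Cohen's $d$ values are taken as given; the package does not recompute
  effect sizes from raw study statistics, and heterogeneity of the
  underlying measurement instruments is inherited from the sources.
- Cost comparability rests on the CPI and wage tables supplied; no
  purchasing-power-parity conversion is attempted.
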