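---
title: "Estimating product reach from supply and use data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating product reach from supply and use data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachcalc)
```

## The problem

Social-impact interventions often deliver a *product* — fortified foods,
supplements, contraceptives, latrines, bed nets, menstrual cups, water
filters — and the question program managers must answer routinely is: *how
many individuals did the product reach?* Direct beneficiary registers or
coverage surveys are expensive and rare in the settings where these
programs operate, but supply-chain data (production, dispatch, sales,
distribution) is usually available from the implementing partners.
`reachcalc` converts that supply-side data, combined with measured or
assumed consumer use patterns, into a defensible headcount: the number of
individuals in a defined area for whom a defined quantity of the product
was available during a defined period.

Reach is an availability/accessibility proxy, not an impact measure: it
estimates how many people a per-consumer quantity of product *could* serve,
under explicit assumptions about who uses how much, how often.

## The model

Reach can be estimated two ways:

* **Coverage route (F1).** If a coverage survey exists, reach is simply
  coverage × the matching population:
  $R = H \cdot I$. The same identity converts any supply-based reach
  estimate back into coverage for triangulation.

* **Supply route.** Otherwise, total supply $A$ in the defined area
  (either sales/dispatch volume $a_1$, or production − exports + imports
  $a_2$, optionally shrunk by a leakage fraction for supply leaving the
  area) is adjusted for quality and post-production losses to give the
  *effective supply*

  $$F_4 = A \cdot b_1 \cdot c_1, \qquad b_1, c_1 \in [0, 1],$$

  the quantity of on-specification product actually available to
  consumers. Both factors default to 1 — the reach-maximising "no loss"
  assumption — and every applied default is recorded in an assumptions
  ledger so the estimate's provenance is explicit.

  For a **fast-moving** good, per-consumer use over the period is
  $F_6 = f \cdot g$: the effective daily amount $f$ (a base daily amount
  chained through named multiplicative adjustments and a unit-conversion
  divisor) times the number of use days $g$. Reach is
  $R = F_4 / F_6$ (formula F3).

  For a **durable** good, each of $U$ supplied units serves $D$ users, and
  a consumer goes through $E$ units during the period (the *turnover*:
  period length ÷ length of use, floored at 1). Reach is
  $R = U \cdot D / E$ (formula F2). We divide by turnover even though the
  source material describes $D$ "multiplied by" $E$: multiplication is
  dimensionally inconsistent with the turnover rationale it accompanies
  (a user who replaces a menstrual cup yearly accounts for five cups over
  five years, so five units must map to *one* person, not five), and
  division is the reading consistent with the worked examples.

  A **razor-and-blade** product (durable "razor" plus consumable "blade",
  e.g. a water dispenser with filter refills) is estimated component-wise:
  if only one component has data, its estimate stands for the bundle; if
  both do, both are reported and the minimum is the combined estimate,
  since using the complete product requires holding the durable *and*
  buying refills. The source material states no combination rule; the
  minimum is the conservative choice and both raw values are preserved.

**Segments and subgroups.** When consumers fall into groups with very
different use patterns (e.g. repeat buyers vs triers), each segment claims
a share of the effective supply and is divided by its own per-consumer
use; the total is the sum of segment headcounts. Population subgroups
(women of reproductive age, young children, socio-economic classes) are
allocated after the fact as total reach × population fraction, under a
homogeneous-use assumption that is recorded in the ledger. Subgroups may
overlap, so their fractions are deliberately *not* required to sum to 1,
while segment supply shares are.

**Monthly series.** Reach can be computed per month to show trends, but
the monthly series refuses to be summed (`sum()` raises an error): the
same individual typically uses the product in many months, so adding
monthly headcounts double-counts people. A period total must come from
aggregating supply over the whole period and estimating once.

## Rounding policies

Published worked examples chain *printed* (rounded) intermediates, so an
implementation carrying full floating-point precision cannot match their
digits exactly. The pipeline therefore takes an explicit rounding policy:

* `full_precision` (default): intermediates at full precision; only final
  headcounts are rounded, half-up, to whole persons.
* `replication`: additionally rounds the effective daily amount to 0.1 g,
  per-consumer period mass to 1 g, and per-segment supply to 0.01 metric
  tons — the precisions a desk calculation prints.

Half-up rounding (0.5 away from zero) is used at every rounding point
because that is how desk calculations round; base R's `round()` rounds
half to even and diverges on exact halves. Internally all mass is carried
in grams (1 MT = 10⁶ g) and durables as unit counts; periods are whole
calendar months (first day of the start month through the last day of the
end month), the only convention consistent with the worked case below.
The "one month" of a short-term consumer uses the 30.4-day convention
(365/12 to one decimal); this deliberately does not equal the per-month
average of any specific period (a 27-month, 819-day window averages
30.33 days), and the two constants are kept as quoted, not reconciled.

## The Brazil fortified-rice case

The packaged fixture encodes a voluntary fortified-rice introduction in
Brazil, February 2013 – April 2015 (27 months, 819 days): 11,174.56 MT
dispatched to retailers; quality and losses factors 1; 160.3 g cooked rice
per capita per day, adjusted by the 85% share of rice eaten at home and
the 60% fortified share of home rice, converted to dry mass by dividing by
2.5 (32.7 g/day); repeat consumers (82% of buyers) consuming over the full
period (26,781 g each) and trial consumers (18% of supply) consuming for
about one month (994 g each); subgroup fractions 28.14%, 6.54% and 74.1%.

```{r brazil}
cfg <- load_config(brazil_fixture_path())
estimate_reach(cfg, "replication")
```

Under the replication policy every intermediate and headcount of the
worked case is reproduced exactly; under `full_precision` the total
differs by about 0.01% (2,365,459 vs 2,365,712), which is the footprint of
chained printed rounding, not a model difference. The per-capita
consumption figure is treated as per-consumer (the case assumes everyone
consumes rice); where that is not true, a consuming-fraction multiplier
expresses the same adjustment through the ordinary multiplier mechanism.

The companion monthly supply ledger
(`brazil_fixture_path("ledger")`) is *synthetic*: only the 27-month total
is reported, so the CSV spreads it near-uniformly (26 months of 413.87 MT
plus a 413.94 MT remainder month, summing exactly). It exists to exercise
ledger ingestion and the monthly series, not as observed monthly data.

## Scenarios and sensitivity

Where inputs are assumptions rather than measurements, the recommended
practice is to bracket the estimate with labelled scenarios
(`run_scenarios()`): e.g. for a staple food with unknown consumption,
"recommended serving every day" (the conservative, *low*-reach bound —
higher assumed use means fewer people served per ton) against "one serving
once" (the high bound). Reports name scenarios rather than saying
"best/worst", because the direction depends on which side of the model the
assumption sits. `sensitivity_sweep()` generalises this to a
one-parameter sweep; multi-parameter grids are out of scope, matching the
one-dimensional reasoning the method prescribes. Reach is weakly
increasing in supply-side parameters and weakly decreasing in use-side
parameters, which the test suite checks as an invariant.

```{r scenarios}
run_scenarios(cfg, list(
  scenario_spec("as_measured",   list("supply.quality_factor" = 1)),
  scenario_spec("half_quality",  list("supply.quality_factor" = 0.5))
), "replication")
```

## The synthetic-config generator

`generate_synthetic_config()` draws valid configurations from ranges
chosen to look like realistic program data — supply of 10–5,000 MT (or
100–100,000 durable units), adjustment factors in [0.7, 1], leakage up to
20%, base daily amounts of 5–300 g with up to three adjustment multipliers
in [0.3, 1], periods of 1–36 whole months, optional repeat/trial
segmentation — and bundles the closed-form full-precision reach computed
by direct arithmetic inside the generator. That bundled truth is an
independent oracle: the test suite checks engine output against it for
1,000 seeds across the three product types. What the generator emulates is
the *arithmetic structure* of real programs, not real data: it draws
parameters independently (real supply and consumption co-vary), has no
seasonality, no measurement error, and no reporting gaps, so passing these
tests demonstrates arithmetic correctness of the pipeline, not robustness
to messy inputs.

## Numerical and design notes

* Validation reports *all* configuration failures at once, and applied
  defaults are logged, not silent.
* Degenerate inputs: zero supply gives zero reach; zero per-consumer use,
  zero population (for coverage conversion), and exports exceeding
  production + imports are errors, distinguished as arithmetic failures
  (CLI exit code 3) from validation failures (exit code 2).
* Segment shares must sum to 1 within 1e-9; household-distribution weights
  likewise. Turnover is returned unrounded — it is a rate, only headcounts
  are rounded.
* Contraband or informal imports enter as ordinary imports; unsold excess
  supply is expressed through the leakage fraction. Neither needs separate
  arithmetic.
* Report files are bit-stable (sorted keys, fixed precision, no
  timestamps), so reruns are byte-identical and diffable.
* Test problem sizes (1,000 random configurations for conservation and
  oracle checks, 500 for the segmentation oracle, 200 random periods for
  the calendar check) were chosen as comfortably large for a pure
  arithmetic pipeline; the whole suite runs in seconds.

## Limitations

Reach is not impact, and supply-based reach measures availability, not
confirmed use; triangulate against coverage surveys when they exist
(`report_bundle()` reports both routes and their ratio when possible).
Point estimates carry no uncertainty intervals — uncertainty is expressed
only through labelled scenario bounds, by design. Scenario bounds are
reported for totals only, not per subgroup. Periods are whole calendar
months; partial months are rejected rather than prorated, since the
convention for them is undefined in the method this package implements.
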