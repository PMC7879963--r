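---
title: "A transparent stock-flow policy model and its validation harness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A transparent stock-flow policy model and its validation harness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

prevsim implements a population system-dynamics simulator of the class used
for cardiovascular and related chronic-disease policy analysis, together
with the validation harness such models require before anyone should trust
them: one-way parameter sensitivity analysis, base-versus-intervention
scenario differencing with health-economic arithmetic, and external
validation against surveillance series with guarded multiplier
recalibration. This vignette is the package's own account of the model, the
numerical choices, and what the shipped desk-scale fixture does and does not
demonstrate.

## The model

### Stocks, flows and the annual step

The engine (`sf_spec()`, `sf_simulate()`) advances named stocks — population
compartments in persons, or fractions such as a prevalence — on a fixed
one-year step. Stocks are measured at January 1 of each year; flows act over
the following year. The integrator is forward Euler with all flow rates
evaluated simultaneously from the prior year's state, so the result does not
depend on the order in which flows are declared. Annual reporting is all the
application requires; no sub-annual dynamics are claimed, and continuous-time
or stochastic integrators are deliberately out of scope.

Rate expressions are restricted to a small arithmetic grammar (`+`, `-`,
`*`, `/`, parentheses, numbers, named symbols). This keeps model files fully
declarative — a spec can be audited symbol by symbol, and loading one can
never execute arbitrary code. Expressions are parsed once at load;
`validate_spec()` returns the complete list of findings (unknown stocks,
unresolved symbols, duplicate parameters, grammar violations) rather than
stopping at the first.

Two numerical conventions matter:

* **Negative stocks.** If the year's net outflow would drive a stock below
  zero, the level is clamped at zero and the deficit is logged on the
  trajectory (`clamp`, `clamp_total`), never silently redistributed. A
  nonzero clamp total is a visible mass-balance warning, and the shipped
  fixture runs with a clamp total of exactly zero.
* **Conservation.** In a closed system (no flows across the boundary) total
  persons are conserved to 1e-9 relative tolerance over the full horizon;
  this is a standing test, not an assumption.

### The epidemiological layer

The disease model tracks adults in two subpopulations: `non_cvd` (no prior
cardiovascular event) and `post_cvd` (at least one). Non-CVD adults
experience first CVD events at a population-average rate

    rate(y) = base_rate * prod_i (1 + p_i(y) (RR_i - 1)) / (1 + pref_i (RR_i - 1))

over risk factors i (smoking, obesity, blood pressure, cholesterol,
diabetes, psychological distress, secondhand smoke, each with current and
borderline strata where relevant). The normalization by the reference
prevalences `pref_i` makes `base_rate` the rate observed at the reference
exposure mix, so the relative risks redistribute risk rather than inflate
it. Joint risks are combined multiplicatively and independently — no joint
distribution is published for such factor sets, and the multiplicative form
is the one consistent with attributable-fraction accounting. Borderline
categories are separate strata with their own (smaller) relative risks
rather than a graded dose-response.

A case-fatality fraction of first events dies (`deaths_cvd`); survivors move
to `post_cvd`, whose recurrent fatal-event rate is the non-CVD rate times a
ratio constrained to be at least 1 — the severity ordering that motivates
tracking the subpopulations separately. Background non-CVD mortality applies
per subpopulation, and a net aging/migration inflow enters `non_cvd`.
Population balance (change = inflow − deaths) closes to 1e-9 each year.

Non-CVD outcomes attributed to exposures use the Levin population
attributable fraction, `PAF = p (RR - 1) / (1 + p (RR - 1))`, applied to an
outcome total: attributed deaths and hospitalizations are the attributable
share of the simulated background-cause totals, which is exactly the
attributable-fraction costing convention used on the economics side.
Protective exposures (RR < 1) are rejected for attribution rather than
producing negative burdens. The standalone `advance_population()` also
accepts explicit attribution outflows with fixed baseline totals for uses
outside the toy nation.

Youth obesity is a tracked measure but children are not an age-structured
cohort: adult obesity is an endogenous fraction stock whose net flow is an
adult-onset drift plus an annual aging transfer, `aging_frac *
(p_youth - p_adult)`, the simplest coupling that lets childhood interventions
propagate into adult risk with a realistic lag.

### Calibration multipliers

Every surveillance-comparable measure has a calibration multiplier parameter
(`mult_<measure>`, default 1) entering only that measure's output
expression, multiplicatively. Two consequences are deliberate: each
measure's output is exactly linear in its own multiplier (so recalibration
is a closed-form least-squares problem), and recalibrating one measure
cannot change any other measure's series even in the last bit — an
independence property the test suite asserts with `identical()`. The
multipliers scale outcome generation for reporting; they never feed back
into the population dynamics, and they are never applied to surveillance
data.

## Levers, scenarios and economics

A lever is a 0-1 control mapped linearly onto one or more parameters:
`parameter' = parameter + movement * max_effect`. Linearity in movement is
the minimal documented choice when only scalar movements (for example 0.53,
0.70, or a 1.9% price-translation) are ever reported; movements are held
constant over the horizon (no ramp-in). `translate_price_policy()` converts
a price policy into a pricing-lever movement as price change times the taxed
goods' consumption share.

`run_scenario()` differences the intervention run against the base run (all
levers zero) over a closed outcome window, 2018-2040 by default (23 years).
Deaths and events averted are base minus intervention; cost changes are
intervention minus base, so savings are negative. Implementation costs are
per-lever annual streams proportional to movement; medical cost changes
price only the costed outcome classes at their unit costs
(attributable-fraction costing, not total-spending differences).
Discounting uses a 3% annual rate, end-of-year convention counted from the
discounting base year (the first window year by default): a base-year
payment is undiscounted and a payment t years later is divided by
(1.03)^t. The convention is test-pinned because the rate alone does not
determine it. Ledgers carry an explicit currency base year; combining
mismatched cost years is an error, never a silent conversion.
`cost_per_death_averted()` refuses to divide by a non-positive denominator
and returns a flagged sentinel; the reporting helper rounds to the nearest
$10,000 with commercial (half away from zero) ties.

## One-way sensitivity analysis

`one_way()` varies one parameter at a time between its plausible low and
high bounds, all other inputs at defaults, and expresses each outcome as a
percent change against the shared base run — the base run is computed
exactly once, and the denominator is always the base-run cumulative outcome,
never the per-bound run. Failed runs become flagged records rather than
aborting the sweep, so a large sweep is restartable and auditable.
`influential()` filters at a threshold using "at or above" semantics
(default 0.5%) and sorts descending by influence with alphabetical
tie-breaks; `tornado_table()` exports the same ordering with the base
outcome carried in metadata. The harness is verified record-for-record
against a naive loop re-implementation.

## External validation and recalibration

"Deviated substantially from surveillance" is a judgment call in practice;
here it is an explicit, reproducible rule with configurable thresholds
(`fit_thresholds()`): a measure is *deviating* iff its mean absolute percent
error over the overlapping years (at least 3 required) exceeds 10%, or the
OLS trend slopes of model and observations disagree in sign with both
magnitudes above a noise floor, which defaults to the standard error of the
observed slope. Relative error is used throughout so count measures
(deaths) and percent measures (prevalences) are treated uniformly.

Recalibration is guarded against over-calibration twice. First,
`recalibration_review()` selects only measures that are deviating *and*
whose residual keeps a constant sign over at least 3 consecutive
observations — transient oscillation around the model is never calibrated
away. Second, the fit itself is minimal: a constant multiplier fitted by
closed-form least squares on relative error, escalating to a log-linear
(in year) multiplier path only when the constant fit cannot reach an
aligned verdict. Both modes are provided because nothing constrains the
shape a priori; the pipeline prefers the more parsimonious one. Every
recalibration result reports the post-fit diagnostic and a cross-effect
table over all other measures.

## The toy nation fixture: what it is and is not

`make_toy_nation()` generates a complete desk-scale parameterization: one
million adults, 2010-2060, 25 surveillance-comparable measures, six levers
(smoking quit services, energy-dense food pricing, physical activity in
schools and in child care, blood-pressure control, quality acute and
rehabilitation care), a 12-row bounds table and a cost ledger. All numeric
values are openly fictitious fixture choices, with five exceptions taken as
fixed study conditions: the quality-of-care bound pair (0.43, 0.90), the 3%
discount rate, the 0.5% influence threshold, the 2018-2040 outcome window,
and the 2010-2060 horizon.

Design choices a reader should know about:

* **Influence balance.** The fixture is built so that no single parameter
  moves cumulative CVD deaths averted by more than 5%, with the
  quality-of-care effect the most influential — the signature of a large
  multi-risk-factor system in which no one input dominates. Concretely,
  averted deaths are spread across several strong prevalence levers while
  the quality lever reaches a 5% slice of events, and bounds reflect how
  well each input is measured: ±3% for event incidence and case fatality,
  ±5% for relative risks, ±10% for behavioural and demographic inputs, and
  the full printed range for the quality-of-care effect. With those
  conditions the sweep's maximum influence is about 3.4% (quality of care),
  with the expected asymmetry between its low and high bounds.
* **Trend identifiability.** Factor drifts are either flat or steep enough
  (≳1.5%/year relative) that the sign of a trend is identifiable from the
  short, noisy sampling windows the panel emulates; drifts of the same
  order as the noise-induced slope error would make the sign-conflict rule
  fire on noise, which is exactly the over-calibration failure the review
  policy exists to prevent.
* **The surveillance panel.** `make_surveillance_panel()` samples each
  measure on a survey-like window (biennial three-cycle windows for
  examination-survey prevalences, annual 2010-2016 for vital statistics,
  and so on), multiplies by a planted multiplier path, and applies
  lognormal noise (2% relative standard deviation by default) so counts
  stay positive. Four measures are planted as persistent deviators — adult
  obesity (constant 1.30), CVD deaths (log-linear drift, 6%/year),
  diabetes-related non-CVD deaths (1.25) and distress-related non-CVD
  deaths (0.80); the full cycle recovers exactly these four and aligns all
  25 measures after recalibration. Planted multipliers are recovered to
  1e-6 without noise and within 5% at 2% noise.
* **What the panel does not emulate.** Survey weights, clustering,
  measurement-error structure, and revisions of real surveillance systems;
  the lognormal-noise panel is a stand-in with the right shape only.
  Passing these tests shows the machinery is correct and the guards work —
  it does not show that any real national model is well calibrated.

Problem sizes were chosen to keep the full cycle desk-scale: the base run
simulates 51 years of 3 stocks, 7 flows and 30 output expressions in about
0.1 s; the 12-bound sensitivity sweep is 25 scenario evaluations; the
complete fixture generation, base run, sweep and validation cycle completes
in well under a minute on one CPU.

## Known limitations

* No age, sex or race stratification, and no community profiles; health
  disparities cannot be examined in this structure.
* Forward Euler at Δt = 1 year ties rate parameters to the annual
  convention; very high annual rates (outflows approaching a stock's level)
  engage the clamp rather than a finer integration.
* The lever-to-parameter response is linear and constant over the horizon;
  diminishing returns or ramp-in must be expressed through the config, not
  inferred.
* Attribution assumes independently acting exposures; overlapping causal
  pathways (for example obesity and diabetes) are not disentangled beyond
  the multiplicative normalization.
* Infectious disease and indirect/productivity costs are out of scope, as
  are QALYs.
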