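---
title: "Societal costing of digital and face-to-face osteoarthritis care: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Societal costing of digital and face-to-face osteoarthritis care: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oacost)
```

## The question

First-line care for knee and hip osteoarthritis — education plus supervised
exercise — can be delivered face-to-face in group sessions at a clinic or
through a digital platform with asynchronous physiotherapist support. The two
delivery models consume very different resources: the face-to-face model needs
clinic facilities, staff hours per group, and repeated patient travel; the
digital model needs platform support and small amounts of asynchronous
clinician time, and the patient exercises at home.

`oacost` implements a societal micro-costing comparison of the two models.
"Societal" means costs are counted wherever they fall, in three domains:

* **system** — provider time, administration, technical support, training;
* **patient** — the patient's own time in contact with care, administration,
  travel time, and direct fees;
* **other** — the monetized carbon emissions of patient travel.

On top of the per-episode unit costs, the package computes incremental
cost-effectiveness ratios (ICERs) on pain outcomes, deterministic and
probabilistic sensitivity analyses, and program-level substitution scenarios.

## Valuation rules

All time valuation is parameterized by a `valuation_context()`:

| Parameter | Default | Unit | Role |
|---|---|---|---|
| `provider_gross_hourly_wage` | 187.2 | SEK/h | physiotherapist gross wage |
| `population_gross_hourly_wage` | 196.58 | SEK/h | average patient gross wage |
| `social_fee_rate` | 0.3142 | fraction | employer social fees on provider time |
| `facility_surcharge` | 0.10 | fraction | overhead on *on-site* provider time |
| `leisure_fraction` | 0.30 | fraction | value of leisure time relative to the gross wage |
| `user_fee_ceiling` | 1100 | SEK | annual out-of-pocket fee cap per patient |
| `training_wage_multiplier` | 1.5 | — | course cost relative to wage cost of training hours |
| `fx_usd_per_100_sek` | 10.2 | USD | exchange rate for the carbon price |
| `reference_year` | 2018 | — | price year of all monetary defaults |

The human capital method is applied throughout:

* **Provider time** is valued at the gross wage times `(1 + social_fee_rate)`,
  with an additional `(1 + facility_surcharge)` factor when the contact takes
  place on clinic premises.
* **Patient contact time** is valued at the full gross wage (production loss).
* **Patient travel time** is valued at `leisure_fraction` of the gross wage.
* **Group sessions** are costed once and divided by the average group size to
  obtain the per-patient share; the undivided (payer-view) cost remains
  retrievable.
* **Training** of providers is amortized: hours × wage ×
  `training_wage_multiplier` × `(1 + social_fee_rate)`, divided by the number
  of episodes a trained provider supports.
* **Technical support** is an annual budget divided by the annual patient
  count, optionally halved for a care model that uses the supporting
  infrastructure less.
* **Direct fees** are capped by the user-fee ceiling.

## Care models as data

A care model is a `care_model_spec()`: a list of `contact_event()`s (mode,
duration or duration range, occurrences, who attends, group size, on-site
flag, participation class), administrative overheads, training and support
parameters, a transport profile, and pain effects. The two models of interest
ship as YAML under `inst/extdata/` and load with `read_care_model()`:

```{r}
ctx <- read_valuation_context(oacost_example("valuation.yaml"))
ja <- read_care_model(oacost_example("ja.yaml"))    # digital
boa <- read_care_model(oacost_example("boa.yaml"))  # face-to-face
build_episode_schedule(ja)[c("contact_count", "provider_minutes_rounded")]
```

The digital episode schedules 18 physiotherapist-attended contacts totalling
143 minutes (rounded half-up from 142.5): three 15-minute telephone calls plus
fifteen asynchronous platform contacts of 5–8 minutes each, taken at their
midpoint (6.5 minutes) under the default `midpoint_policy`.

## Calibration to the published unit costs

The cost tables this package reproduces were published only in rounded,
whole-SEK form, and the underlying unit-level source data are not available.
The shipped YAML fixtures are therefore *calibrated*: hours and wage inputs
were chosen so that every published line item, domain subtotal, and total is
reproduced exactly under half-up rounding, while all valuation *rules* are the
ones described above. Two calibration choices deserve mention:

* In the digital model, synchronous telephone time is booked under provider
  **contacts** while asynchronous platform time is booked under
  **administration**, matching how the published table splits clinician
  effort. The fixtures encode this with explicit contact-hour overrides.
* A small number of published aggregate figures are arithmetically
  inconsistent with their own components (for example the total monetized
  emissions figure). These are recorded in `published_figures()` with
  `reproducible = FALSE` and a note, and are deliberately *not* asserted
  numerically anywhere.

```{r}
render_breakdown_report(list(cost_model(boa, ctx), cost_model(ja, ctx)))
```

The totals are 10 611 SEK (face-to-face) and 2 776 SEK (digital); the
difference is 7 835 SEK per episode.

## Cost-effectiveness

Effects are 12-week pain reductions on a 0–10 numeric rating scale: 5.7 to 3.2
(a 44 % reduction) for the digital model and 5.2 to 4.1 (21 %) for
face-to-face. The ICER compares the digital model (a) against face-to-face
(b):

$$\mathrm{ICER} = \frac{C_a - C_b}{E_a - E_b}
               = \frac{2776 - 10611}{3.2 - 4.1} \approx 8706$$

`icer()` keeps the full-precision ratio but also reports the integer ratio
obtained by truncation toward zero, and classifies the dominance quadrant
(here: *dominant* — cheaper and more effective).

```{r}
icer(2776, 10611, 3.2, 4.1)[c("ratio", "ratio_reported", "quadrant")]
```

Note the reported ratio of 8 705 SEK per pain point follows the convention of
computing the ratio from the whole-SEK rounded unit costs and truncating;
computing from unrounded costs gives 8 706. The package exposes both.

`one_way_dsa()` re-evaluates any cost function over parameter ranges;
`psa()` draws gamma-distributed costs and truncated-normal effects, and
`ceac()` turns the draws into a cost-effectiveness acceptability curve.

## Substitution scenarios

`substitution_scenario()` models moving a share $s$ of the annual
face-to-face volume (9 465 episodes) to the digital model. Two modes exist:

* **standard** — savings are $s \cdot n \cdot (C_b - C_a)$, the natural
  budget-impact formula;
* **as_printed** — reproduces the published scenario table, whose rows keep a
  constant row sum equal to the full face-to-face baseline
  ($9\,465 \times 10\,611$ SEK) and whose remaining costs stand in exact
  ratio 3:2:1 across $s = 25/50/75\,\%$.

The two modes answer different questions and are never mixed; the mode is an
explicit argument and is echoed in every result.

## Transport and emissions

A face-to-face episode entails 28 round trips of 52.5 minutes. Travel time is
a patient cost at leisure valuation; emissions are 0.014 tonnes of CO₂ per
episode, so a 9 500-episode program emits 133 tonnes. Emissions are monetized
at a market carbon price (default 220 USD per tonne at 10.2 USD per 100 SEK);
the face-to-face fixture carries an effective calibrated price of 4 200
SEK per tonne, which is what reproduces the published per-episode emissions
line of 59 SEK.

## Synthetic cohorts

The published analysis is mean-based; to make the pipeline testable bottom-up
the package generates synthetic episodes with `generate_cohort()`:

* scheduled occurrences are thinned binomially by per-class participation
  rates (exercise sessions 0.60, co-patient lectures 0.44 by default);
* contact durations get truncated-normal jitter around the schedule;
* patient wages are lognormal around the population wage;
* travel times are truncated-normal; pain scores truncated-normal on [0, 10].

All dispersion parameters are package conventions, not published estimates.
Generation runs entirely inside `withr::with_seed()`, so results are
reproducible and the global RNG stream is untouched. A zero-variance
configuration (all standard deviations 0, participation rates 1) reproduces
the deterministic unit cost **bit-for-bit**, which pins the per-episode
costing to the aggregate engine. The test suite also checks stochastic
recovery: with default jitter, the mean of 10 000 synthetic digital episodes
falls within three standard errors of the deterministic unit cost. Cohort
sizes used in tests (4 000–10 000) are a package choice balancing statistical
power against runtime; passing these tests shows the generator is centred and
reproducible, not that the dispersion magnitudes reflect any real population.

## Numerical conventions

* **Half-up rounding.** Published tables use commercial rounding (0.5 rounds
  away from zero), not R's banker's rounding; `round_half_up()` implements it
  and is applied *only at presentation*. All internal arithmetic is full
  precision.
* **Truncation for the reported ICER.** The integer ICER is truncated toward
  zero, matching the published convention.
* **Midpoint policy.** Duration ranges resolve to their midpoint by default;
  `low` and `high` policies support sensitivity analysis.
* **Accumulation order.** Per-episode synthetic costs are summed per domain
  and then across domains, in the same order as the aggregate engine, so the
  zero-variance equality holds to the last bit.

## Limitations

* Unit costs are calibrated to rounded published values; component-level
  inputs (exact wage rates, hours) are reconstructions consistent with the
  stated rules, not source data.
* Effects come from separate evaluations of the two models, not a randomized
  head-to-head comparison; the ICER should be read accordingly.
* The synthetic generator's dispersion parameters are conventions for
  testing, not estimates.
* Monetary values are in 2018 SEK; no discounting is applied (the horizon is
  12 weeks).
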