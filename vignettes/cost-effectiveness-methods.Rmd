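---
title: "Methods: decision-tree cost-effectiveness of franchise-based ORS-Z promotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision-tree cost-effectiveness of franchise-based ORS-Z promotion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(franchiseCEA)
```

## The question and the model

A social franchise is an NGO-coordinated network of private health
providers who receive a subsidized commodity, training and supervision
under a common brand. This package evaluates whether using such a
franchise to promote a co-packaged oral rehydration salts + zinc (ORS-Z)
kit for childhood diarrhea is worth its cost, compared with leaving
distribution to government clinics and the open market. The evaluation
is population-based: costs and health effects are normalized to a
standard community of 1 million people (81,000 children under 5;
48,373 diarrhea episodes per year at 59.7 episodes per 100 child-years),
so the result speaks to a public-health planner choosing a delivery
strategy, not to a clinician treating one child.

The episode model is a two-arm decision tree with four terminal nodes
per arm. An episode first splits on whether formal care is sought
(probability `p_seek`), then on whether the child receives ORS-Z
conditional on that choice, giving nodes A (seek, ORS-Z), B (seek,
none), C (no seek, ORS-Z), D (no seek, none). Node costs are sums of
ingredients: the consultation fee where care is sought, the societal
unit cost of the kit where ORS-Z is received, and a household penalty —
the expected cost of hospitalization ($0.07) plus one day of caregiver
time valued at GDP per capita per day ($1.28) — where it is not.
Expected cost per episode is the fold-back
$\mathbb{E}[c] = \sum_i p_i c_i$, and the incremental cost of the
intervention is the difference of the two arms' expected costs scaled
to 48,373 episodes.

Health effects do not flow through the tree. The surveyed coverage
increment (6.1% to 13.7% in the intervention area, a 7.6-point pre-post
increase; 10.6 points as a difference-in-differences against the control
area's 4.8% to 1.8% drift) was converted to deaths averted by an
external lives-saved model, and the package takes that output as an
input distribution: Normal(2.85, 0.29) deaths averted per million
population, truncated at zero, with a deterministic base-case value of
2.4253 (the value implied by the published base-case cost per death).
Deaths become DALYs through a fixed constant of 27.06 years of life
lost per death; morbidity is treated as negligible.

## Value-chain costing

The kit's societal unit cost is assembled from payer-tagged stages:
factory production $0.35, packaging $0.02, launch amortization $0.07,
administration overhead $0.09, franchise distribution $0.13, and the
provider's retail service $0.12 — $0.78 per kit in total. The financing
decomposition is different from the cost-bearing one: the household
pays the $0.35 retail price and donors finance a $0.43 subsidy, while
the provider's wholesale outlay and retail revenue net to their $0.12
margin. `subsidy_ledger()` exposes both decompositions because both are
meaningful — the first answers "who uses resources", the second "who
ultimately pays" — and both must sum to $0.78 exactly. Currency is
carried in exact cents inside the chain so that printed-table aggregates
are reproduced to the cent; amounts are 2010 US dollars throughout.

Launch amortization is straight-line over a 10-year horizon divided by
forecast unit sales, with an optional annuity discount rate defaulting
to 0 (plain straight-line). Overhead allocation multiplies two shares —
the franchise program's share of the organization (~33%) and the
product's share of franchise commodities — over annual units. Neither
the absolute launch budget nor the forecast volume behind the published
$0.07/unit is printed anywhere, so the model pins the per-unit results
directly and exposes the operations generically.

## Calibrating the tree from printed tables

The published material gives, per node, the cost per event $c_i$ and the
probability-weighted cost per diarrhea $r_i$ rounded to the cent — but
not the probabilities. `calibrate_node_probabilities()` back-derives
them: it requires $\sum_i p_i = 1$ exactly while keeping each
$p_i c_i$ inside the half-cent rounding band of the printed cell,
i.e. $|p_i - r_i/c_i| \le 0.005/c_i$. The naive ratios $r_i/c_i$ sum to
slightly under one (rounding losses), and the shortfall is spread across
nodes in proportion to each node's slack width — a rule that stays
inside every box constraint whenever the constraint set is feasible at
all, and reduces to the ratios themselves when they already sum to one.
Infeasible inputs signal a calibration failure reporting the residual.

One arithmetic subtlety follows from calibrating against rounded cells.
Because the printed per-diarrhea column was rounded before being summed,
the published per-episode totals ($2.16 intervention, $1.83 control) are
sums of cent-rounded cells; any probability vector that both sums to one
and honors the rounding bands yields an exact fold-back of about $2.18 /
$1.85. The package therefore carries both conventions:
`method = "as-printed"` (the default for `base_case()`) rounds each node
subtotal to the cent before summing, reproducing the published
deterministic chain to the cent — per-episode costs, the $15,963
incremental cost, and the base-case ICERs of $243 per DALY and $6,582
per death; `method = "exact"` is the mathematically consistent
expectation and is what the Monte Carlo analysis uses (rounding inside a
sampling loop would be indefensible). The two differ by about 1% — pure
accumulated rounding.

In the control arm the kit carries only the $0.35 factory cost (there is
no franchise chain to finance) and the household penalty only the $1.28
caregiver component, following the published node-cost footnotes; the
intervention arm uses the full $0.78 and $1.35.

## Effectiveness details

The headline coverage increment is the 7.6-point pre-post difference,
matching the source's own choice (the control change was insignificant);
the DiD estimator (10.6 points) is available via `effect = "did"` in the
pipeline and is recorded in the run log. Binomial standard errors use
$\sqrt{p(1-p)/n}$; the formula printed in the source,
$p(1-p)\sqrt{N}$, exceeds one for any appreciable $N$ and is plainly a
typographical slip, but is retained behind `paper_formula = TRUE` so the
discrepancy can be audited rather than silently corrected.

The DALY constant deserves a note: the stated discounting inputs (3%
per year, life expectancy 65, an under-5 mean age at death) give about
28 discounted years via the annuity
$(1-(1+r)^{-L})/r$, not the 27.06 implied by the published base case
(65.63 DALYs / 2.4253 deaths). The mean age at death behind the
published constant was never reported, so `daly_parameters()` defaults
to the calibrated 27.06 and `discounted_life_years()` provides the
analytic alternative (discrete or continuous compounding).

## The probabilistic sensitivity analysis

`run_psa()` is a second-order Monte Carlo: each iteration redraws the
full parameter vector and re-evaluates the model. Distributions follow
the published design:

* every unit-cost parameter (six chain stages, hospitalization,
  caregiver time, two consultation fees) is triangular with minimum and
  maximum at ±20% of the base value — mean equal to the base by
  symmetry;
* the six branch probabilities (care-seeking plus the two conditional
  receipt probabilities, per arm) are normal around the calibrated
  values, truncated to [0, 1] by rejection. Their standard deviations
  are binomial standard errors whose denominators are the expected
  episode counts implied by the survey frame (3,200 / 3,382 households
  × 0.597 episodes per child-year, with the expected seek / no-seek
  subsets for the conditional probabilities) — the natural reading of
  probabilities "based on the frequencies in individual children", since
  no effective sample size for them was ever printed;
* deaths averted is Normal(2.85, 0.29) truncated at zero in stochastic
  mode, or a point mass at 2.4253 in deterministic mode. Whether the
  original analysis re-linked sampled coverage to deaths is unstated;
  the independent-input reading is used here, which also means
  effect-side uncertainty is attributed to the deaths parameter rather
  than to the receipt probabilities in the tornado ranking.

Sampling is deterministic given `(seed, iteration)`: each iteration
seeds its own Mersenne-Twister substream and draws parameters in a
fixed order, so runs are bit-reproducible and a single iteration can be
regenerated in isolation. Both costing perspectives are evaluated on
the same draw matrix (common random numbers); the medical perspective
simply zeroes the caregiver-time valuation in both arms, so the
per-iteration difference between perspectives is exactly that draw's
caregiver-time savings on untreated-episode mass. This matters: with
independent streams the incremental quantities would carry avoidable
Monte Carlo noise.

ICERs are computed per iteration as $\Delta C / \Delta E$; iterations
with non-positive effect gain are flagged non-informative and excluded
from ratio summaries (counted separately), and negative-cost iterations
are flagged cost-saving. Summaries report mean, SD (denominator
$n-1$), and median/quartiles by linear interpolation between order
statistics (the source states no quartile convention; this is the common
default). Because the published "average" row mixes a ratio-of-means
with per-iteration medians, `summarize_psa()` emits both the
mean-of-ratios and the ratio-of-means, with the median as the headline.
The tornado is an OLS regression of the per-iteration ICER on
z-standardized parameter draws, ranked by absolute standardized
coefficient, top seven reported; zero-variance and aliased columns are
dropped and flagged. Classification against the
Commission-on-Macroeconomics-and-Health thresholds uses strict
inequalities (below 1× GDP per capita per DALY: highly cost-effective;
below 3×: cost-effective).

At the default problem size — 1,000 iterations over 17 parameters — a
run takes well under a second; all package checks and the full report
pipeline run in a few seconds.

## The synthetic household survey

`generate_survey()` emulates the evaluation survey that the estimators
assume: 3,200 intervention and 3,382 control households, each
contributing one child under 5 observed in a pre and a post round;
episodes are Bernoulli with probability 0.597 per round (the incidence
under a one-year recall window and one child per household — the
simplest structure that exercises every estimator, since household
composition was never described); care-seeking and conditional ORS-Z
receipt are Bernoulli with the design's true probabilities, defaulting
in the post period to the calibrated tree values and in the pre period
to receipt probabilities scaled by the surveyed pre/post coverage ratio
of that arm (care-seeking held constant across rounds); out-of-pocket
costs are the true pathway means under mean-one multiplicative
lognormal noise (σ = 0.5 by default), floored at zero — non-negative
and right-skewed, as observed cost data are.

`estimate_probabilities()` pools individual-level frequencies (never
village averages, matching the source's explicit choice) with binomial
standard errors; `estimate_costs()` takes arithmetic pathway means.
What the generator deliberately omits: village-level clustering and
design effects (the source pools individuals), within-season incidence
structure, recall error, and any correlation between a household's
care-seeking and its cost draw. Passing recovery tests therefore show
that the estimators are consistent for the data-generating process the
analysis assumes — not that the original survey was free of cluster or
recall artifacts.

## Known limitations

* The deterministic and exact arithmetic differ by ~1% (rounding
  accumulated in the printed tables); both are exposed and the choice is
  explicit everywhere.
* The published stochastic means sit a few percent above the base case
  in a way symmetric ±20% distributions cannot produce; the Monte Carlo
  here centres on the model's own base case, and its summaries land
  within a few percent of the published ones rather than on top of
  them.
* Tree-implied ORS-Z coverage (~22% intervention) and surveyed coverage
  (13.7%) are not mutually consistent in the source; both are preserved
  in their respective modules and neither is forced onto the other.
* Deaths averted is an external model's output taken on trust; nothing
  in this package validates the coverage-to-mortality link.

## Reproducing the analysis

The numbered scripts under `analysis/` run the steps in order (unit
costing, tree calibration and base case, effectiveness and the
synthetic-survey check, PSA and report tables), writing their tables
under `results/`. `run_pipeline()` performs the whole sequence in one
call, and `scripts/acceptance.R` recomputes the headline quantities
from scratch for a given seed.
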