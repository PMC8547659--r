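---
title: "Methods: comparative risk assessment of sodium reformulation targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative risk assessment of sodium reformulation targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sodiumcra)
```

## The model and its assumptions

`sodiumcra` estimates the annual deaths, incident cases and DALYs from
cardiovascular disease (CVD), chronic kidney disease (CKD) and stomach
cancer that full compliance with a set of maximum sodium content targets
for packaged foods could avert. It is a comparative risk assessment (CRA):
a static population model that shifts the sodium exposure distribution and
converts the shift into a potential impact fraction (PIF) per outcome and
age–sex stratum. As a CRA it has no time dimension — no lag between
intervention and outcome, no recurrent events, no behavioural response to
reformulation (sales volumes are held fixed pre/post), and no interaction
between individuals. These are modelling assumptions, not omissions: the
model quantifies the *theoretical maximal* impact of full compliance.

The pipeline has four stages.

**Stage 1 — baseline intake.** 24-hour diet recall rows (person × food,
g/d, survey weight) are matched to a composition table (sodium mg/100 g)
and a food-to-category mapping, giving survey-weighted mean sodium intake
per food category per stratum. Foods outside every reformulation program
(restaurant, takeaway, scratch-cooked) map to an untargeted remainder that
is carried through but never reformulated. Because a single 24-hour recall
underestimates intake, all category intakes within a sex are rescaled by
one factor `f_s = share × urinary_s / recall_total_s`, anchoring the sex
totals to the nondiscretionary share (default 0.85) of urinary-excretion-
based intake. The factor is deliberately uniform across categories — the
adjustment cannot change the relative contribution of any category, only
the level. Usual-intake (measurement-error) modelling of single recalls is
out of scope.

**Stage 2 — reformulation.** Within each targeted category the
sales-weighted mean sodium content `Σ(density × kg)/Σ(kg)` is computed
before and after clamping every covered product to the category target
(`density' = min(density, target)`); products already compliant are
untouched. The proportional reduction is `r_c = 1 − post_c/pre_c`. Acting
at product level (not on a generic category mean) is what makes company
attribution possible: a single-company scenario clamps only that company's
products while keeping all sales weights unchanged.

**Stage 3 — intake change.** `Δ_as = Σ_c intake_as,c × r_c`. The standard
error of `Δ` combines the category intake SEs scaled by `r_c` assuming
independence across categories; this is a documented simplification (the
SEs only parameterise one Monte Carlo draw family).

**Stage 4 — health impact.** With intakes converted to mmol/d via the
molar mass 22.99 g/mol, the PIF for outcome *o*, age *a*, sex *s* is the
normalised difference of `∫ RR(x) P(x) dx` between the pre- and
post-intervention intake distributions. CVD and CKD risks are mediated by
systolic blood pressure: the log relative risk per 10 mm Hg (`lnRR_oa`,
age-specific) is chained with the SBP response to sodium
`k_as = main + age_int (age − ref_age) + hyp_int × prevalence`
(mm Hg per 100 mmol/d), giving
`RR(x) = exp(lnRR_oa (k_as/10) (x − TMREL)/100)` above the
theoretical-minimum-risk exposure level and exactly 1 below it. Stomach
cancer uses the direct form `exp(lnRR_a M_Na (x − TMREL)/1000)` per g/d.
Averted events are `PIF × events` per cause and stratum, summed over
strata; CVD totals are sums of the eight subtype estimates. Inflammatory
heart diseases (endocarditis, rheumatic heart disease) develop
independently of blood pressure, so they are excluded from incidence and
DALY totals but retained for mortality, where lower blood pressure still
reduces heart-failure deaths.

## Tunable parameters

| Parameter | Unit | Default | Why |
|---|---|---|---|
| `share` | fraction | 0.85 | nondiscretionary share of urinary-based intake; 0.75 in sensitivity analysis |
| `tmrel` | g/d | 2.0 ± 0.2 | no excess risk below this intake; 1.0 ± 0.2 and 3.0 ± 0.6 as sensitivity bounds |
| `intake_multiplier` | — | 1.0 | 0.9 tests a 10% lower baseline intake |
| `mode` | — | `"delta"` | exposure-distribution family for the PIF (see below) |
| `cv` | — | 0.25 | coefficient of variation of the lognormal intake distribution |
| `draws` | count | 1000 | Monte Carlo simulations |
| SBP coefficients | mm Hg per 100 mmol/d | 3.74 / 0.105 per yr / 2.49 | meta-regression-style dose response; supplied as data, never hard-coded |

## Exposure-distribution choice

The PIF is written as an integral over intake distributions, but a CRA can
be run equally with a degenerate ("shift in mean") exposure. Both modes
are first class:

* `delta`: each stratum sits at its mean; the closed form
  `1 − RR(post)/RR(pre)` applies. This is the default — fast, exact, and
  the natural reading of a mean-shift intervention.
* `lognormal`: intakes are lognormal with the stratum mean and a
  configurable coefficient of variation (default 0.25); integrals use the
  trapezoid rule on a fixed grid of 2,001 points.

The fixed grid avoids adaptive-quadrature nondeterminism. Its upper bound
is the larger of mean + 8 SD and the `1 − 1e-8` quantile of either
distribution; the second term matters because the lognormal right tail is
heavier than eight normal standard deviations. A coverage guard raises an
error if less than `1 − 1e-6` of either distribution's mass falls inside
the grid. The two modes agree to three decimals in the narrow-distribution
limit, which the test suite checks against the closed form.

## Monte Carlo uncertainty

Each of the `n = 1000` simulations draws every uncertain input
independently: per-stratum pre-reformulation intake and reformulation
effect (normal, truncated so `0 ≤ Δ ≤ pre`), hypertension prevalence
(moment-matched Beta, support [0, 1]), the three SBP coefficients
(normal), each cause's log relative risk (normal on the log-RR scale),
the TMREL (normal truncated at zero), and event counts (lognormal, with
sdlog recovered from the 95% UI). None of these families is dictated by
the CRA itself; they follow standard practice for this model class, and
every one has an exact zero-dispersion branch so that a zero-SD
specification reproduces the central run bit for bit. Draws are
deterministic per `(seed, index)` — a longer run reproduces a shorter
run's draws as a prefix, and results are independent of execution order.
Outputs are summarised by the 50th (central) and 2.5/97.5th percentiles
(linear interpolation between order statistics, fixed for
reproducibility). Aggregates are summarised from per-draw sums, so the
median of a total need not equal the sum of component medians — the test
suite demonstrates the difference on the skewed draws. Independent draws
of possibly correlated inputs are a known limitation.

Scenario comparisons difference the two scenarios *per draw* (same seed,
same inputs) before summarising; differencing the interval endpoints
instead would ignore the strong positive correlation between scenarios
and overstate the uncertainty of the increment. Sensitivity runs reuse
the base seed for the same reason: deltas reflect assumptions, not Monte
Carlo noise.

## Numerical and design choices

* **Weighted quantile targets.** The optimistic scenario places each
  category target at the smallest density whose cumulative sales share
  reaches `q` (left-continuous, no interpolation), which guarantees
  literally that at least a fraction `q` of sales volume already complies.
* **Negative SBP effects.** Coefficient draws can push `k_as` below zero
  in the youngest strata; `k` is clamped at zero (no protective effect of
  extra sodium is modelled) and the clamp count is surfaced as a warning
  on the central run.
* **Prevalence weighting.** `k_as` uses prevalence-weighted coefficients
  per stratum rather than splitting strata into hypertensive and
  normotensive sub-populations; simpler, and equivalent at first order.
* **Company attribution** uses independent single-company scenarios (not
  leave-one-out), expressed as shares of the all-company total. The
  intake reduction is exactly additive across companies (the clamp
  excesses partition), and the PIF is near-linear at these small shifts,
  so shares are stable; ranking ties break by company id.
* **Degenerate inputs.** Zero recall totals, zero stratum weights, zero
  category sales, inverted burden intervals, unmapped foods and missing
  burden cells are all hard errors with explicit messages — never
  silently patched. An empty target set is valid and averts nothing.
* **Band edges.** Strata are adults in 5-year bands from age 25,
  collapsing at 80+, two sexes — 24 strata. The edges are configuration,
  not contract.

## What the synthetic generator emulates — and what it does not

The generator reproduces the *structural* features the pipeline relies
on: 24 age–sex strata with age-increasing blood pressure and hypertension
prevalence; right-skewed (lognormal) food intakes and within-category
sodium spreads wide enough that any mid-distribution target splits the
products into compliant and non-compliant sets; a Zipf-concentrated
company market in which a few dominant retailers and manufacturers hold
most sales; survey weights; burden tables with multiplicative uncertainty
sized to the order of national CVD/CKD/stomach-cancer totals; and three
nested target sets (narrow-lenient, broad-strict, broad-25th-percentile)
derived from the generated supply itself.

It does *not* emulate a real food taxonomy, nutrient fields other than
sodium, household-level purchasing, differential underreporting by food
group, or correlation between a person's food choices and their stratum's
risk factors. Passing tests therefore demonstrate that the pipeline's
arithmetic, orderings and uncertainty mechanics are correct under
realistic structure — not that any particular country's numbers are
reproduced. The generator's analytic ground truth (category reductions
recomputable in one pass from the product and sales tables) gives the
end-to-end recovery checks their reference values.

## Problem sizes

The default synthetic bundle uses 500 survey respondents, 16 food
categories (8 covered by the narrow target set) × 12 products, 30
companies and 1,000 Monte Carlo draws; the test suite's property loops
use 150-person, 8-category supplies across 20 seeds. These sizes keep
every stage comfortably estimable (≥ ~20 respondents per stratum) while
the full suite and the acceptance script each run in well under a minute.

## Known limitations

* Single uniform underreporting factor per sex; real underreporting
  differs by food group.
* Independence assumptions: across categories when combining SEs, and
  across all Monte Carlo draw families.
* No direct (non-BP-mediated) sodium effects on CVD/CKD; stomach cancer
  is the only direct pathway.
* Company market shares are assumed identical across age–sex strata.
* The delta mode ignores within-stratum intake dispersion; the lognormal
  mode fixes its shape by a single coefficient of variation.
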