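---
title: "Model and methods: cost-utility analysis of BRCA1/2 risk-reducing strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brcacua)
```

## The decision problem

Women who test positive for a pathogenic *BRCA1* or *BRCA2* variant face a
lifetime risk of breast cancer (BC) around 70% and of ovarian cancer (OC) of
17-44%, depending on the gene. Five risk-reducing strategies available in
Switzerland are compared for a cohort of 40-year-old, cancer-free mutation
carriers:

* **IS** — intensified surveillance (reference): semi-annual gynaecological
  consultations plus age-related imaging (annual mammography + breast MRI to
  59, annual mammography 60-69, biennial mammography from 70).
* **PBM** — prophylactic bilateral mastectomy with breast reconstruction.
* **PBSO** — prophylactic bilateral salpingo-oophorectomy, with hormone
  replacement therapy until the median age of natural menopause (51).
* **PBM&PBSO** — both surgeries at cohort entry.
* **CP** — chemoprevention with Tamoxifen for five years, alongside IS.

The analysis takes the healthcare-system perspective, values outcomes at a
willingness-to-pay of CHF 100,000 per QALY (EUR 90,909 at the fixed rate
1 EUR = 1.10 CHF), and discounts costs and outcomes at 3% per year. The
model is run separately per mutation because penetrance, molecular subtype
mix and chemoprevention efficacy differ.

## Markov structure

Nine aggregate health states — disease-free (DF), BC, contralateral BC
(CBC), metastatic BC (MBC), post-BC, post-CBC, OC, post-OC and dead — are
expanded into 36 states: BC, CBC and OC become 10-year tunnels tracking
years since diagnosis, so cancer-specific mortality, treatment costs and
utility recovery can depend on time since diagnosis. Women who survive ten
years after a cancer diagnosis move to the corresponding post-cancer state
and revert to age-specific background mortality. MBC only arises from
BC/CBC (surveillance detects primary BC early, so direct progression from
DF is excluded) and is terminal. After OC, the only cancer re-entry is
metachronous BC from the post-OC state. A woman entering CBC restarts a
fresh 10-year tunnel.

The cohort starts 100% disease-free at the starting age and runs 60 annual
cycles (to age 100). Rewards are counted on start-of-cycle occupancy and
cycle-t increments are discounted by $(1+d)^{-t}$, cycle 0 undiscounted. No
half-cycle correction is applied by default (`cua_config(half_cycle =)`
enables one), matching the common default of cohort-model software.

### Rates, probabilities and competing risks

All inputs are annual event rates. Conversion to per-cycle probabilities
happens exactly once, inside the engine. Within a cycle, competing exits
from a state use the proportional-split exponential formula: with total
exit rate $R=\sum_k r_k$,

$$p_k = \frac{r_k}{R}\,\bigl(1-e^{-R}\bigr), \qquad p_{stay}=e^{-R},$$

which is order-independent and makes every row of the transition matrix sum
to one exactly. Age-banded rates are looked up with inclusive band bounds;
an age on a printed boundary belongs to the band whose upper bound it
equals (age 40 is in the 31-40 breast-cancer incidence band; the open
"60+" band therefore starts at 61). Where the published mortality bands
overlap as printed ("0-49 / 0-69 / 70+"), they are read as the
non-overlapping partition 0-49, 50-69, 70+, the only reading consistent
with a lookup table. The contralateral-incidence table ends at 80; its last
band is extended to the model horizon.

Background (life-table) mortality applies in DF and the post-cancer states.
Inside the cancer tunnels and MBC, cancer-specific mortality applies *plus*
background mortality as a competing rate. The source material specifies
cancer-specific death rates for ten years after diagnosis but is silent on
concurrent other-cause death; including it avoids an immortal-cohort
artefact in the tunnels and is the package default
(`background_mortality_in_cancer = FALSE` restores the alternative).

### Strategy effects

Strategy effects are hazard ratios on incidence rates, shipped as data
(`inst/extdata/strategies.yaml` + `hazard_ratios.csv`): PBM multiplies BC
incidence by 0.09; PBSO multiplies OC incidence by 0.28 from the
disease-free state and by 0.14 once a woman has had BC (the prior-BC ratio
*replaces* the 0.28); PBSO has no effect on BC incidence; the combined
strategy applies both sets. Tamoxifen's 0.31 applies only to the
hormone-receptor-positive fraction of incident BC (20% in BRCA1, 80% in
BRCA2):

$$r_{CP} = r\,\bigl(f_{HR+}\cdot 0.31 + (1-f_{HR+})\bigr),$$

plus a mutation-specific contralateral effect (0.44 BRCA1, 0.33 BRCA2). The
0.31 figure is printed as a relative risk reduction for ER+ disease in its
source trial; it is applied here as a multiplicative hazard ratio, with
`cp_interpretation = "one_minus_rrr"` available for the complementary
reading. The chemoprevention effect is lifelong in the base case (risk
reduction has been observed up to 20 years); a scenario truncates it at
five years. PBM's hazard ratio is also applied to metachronous BC after OC
in PBM-containing arms — the breast tissue is removed — a package choice,
since the source enumerates the effect only for primary incidence.

## Utilities

Utilities use the multiplicative age-adjustment method: the age-specific
disease-free utility (0.871 at 40-49, 0.842 at 50-59, ...) times a state
multiplier. A woman diagnosed with BC at 50 accrues $0.842 \times 0.637 =
0.536$ in her first year. Disease multipliers (BC/CBC 0.637, OC 0.410, MBC
0.533) apply in the first year after diagnosis and recover linearly to 1 by
year 6:

$$m(t) = u_d + (1-u_d)\frac{t-1}{5}, \quad t = 1,\dots,5,$$

the only linear interpolation with $m(1)=u_d$ and full recovery after five
years. MBC is terminal and does not recover. The OC constant is the printed
0.410 (the mean of its five yearly components, 0.412, is recomputed and
unit-tested but not substituted).

Strategy disutilities apply in the disease-free state: 0.88 (PBM), 0.90
(PBSO), 0.79 (PBM&PBSO) for one year after the cycle-0 surgery; 0.90 for
chemoprevention's five intake years. The surveillance value 0.96 is a
per-examination utility; since imaging continues for decades under the
surveillance schedule, the default applies it in every disease-free cycle
with scheduled imaging (`is_disutility = "first_year"` restores a one-year
reading; the choice materially affects the surveillance QALY total, and the
schedule reading is what reproduces the published QALY gap between
surveillance and surgery). Scenario analyses hold the surgical disutility
constant for 5 or 10 years (no linear recovery), leaving chemoprevention
and surveillance unchanged.

## Costs

Costs are a pure data artifact read from a structured YAML schedule. The
national tariff-derived amounts behind the original analysis are not
redistributable, so the package ships a **synthetic fixture** with
plausible Swiss magnitudes (anchors in `make_cost_schedule()`, chosen once;
e.g. prophylactic mastectomy 11,000 EUR, breast MRI 500 EUR, PARP-inhibitor
maintenance year 45,000 EUR). Every output produced from it is watermarked
"fixture costs". Replacing the file with transcribed tariffs requires no
code change.

The schedule composes, per mutation:

* **BC/CBC years 1-10** — year 1 bundles surgery, reconstruction (95%
  implant / 5% autologous; year 2 instead under the deferred-reconstruction
  scenario), 50% reshaping, radiotherapy weighted by the 38%
  nodal-involvement share, and subtype-weighted chemo-/targeted therapy;
  years 1-5 add endocrine therapy for the HR+ fraction; CBC costs equal BC
  costs.
* **OC years 1-10** — debulking surgery, first-line chemotherapy and
  PARP-inhibitor maintenance (years 1-2), recurrence treatment weighted by
  the 73% relapse share in years 3-5, follow-up throughout.
* **MBC** — annual cost = subtype-weighted total therapy cost divided by the
  subtype's median overall survival.
* **Recurring** — strategy-dependent surveillance in DF and the post states,
  hormone replacement to age 51 in PBSO arms, Tamoxifen plus annual vaginal
  ultrasound during intake, annual vaginal ultrasound in post-OC.
* **Implant replacement** — every 10 years to age 70. In
  prophylactic-mastectomy arms this is charged as a lump sum to the
  surviving cohort at cycles 10/20/30 (an amortised annual mode is
  available); after therapeutic BC reconstruction it is amortised annually
  inside the BC tunnel and post-BC states, and suppressed in PBM arms whose
  implants are already on the prophylactic replacement clock.
* **Palliative care** — a lump sum on every transition from BC, CBC, MBC or
  OC to dead. CBC is included: the schedule treats CBC like primary BC
  throughout. The lump applies to the whole death flow from those states
  (including the small background-mortality share), a simplification.

Hormone replacement is charged to disease-free occupancy only; women in
treatment states are assumed to discontinue it.

## Comparative analysis

Per strategy the model reports discounted lifetime cost, QALYs and LYs;
the league table adds differences versus surveillance, ICERs (computed only
when both increments are positive; dominated comparisons are labelled,
never reported as negative ratios), absolute/extended dominance against the
full strategy set, and net monetary benefit $\lambda\,QALY - cost$. The
frontier is computed independently of the choice of reference.

## Sensitivity and scenario analysis

Probabilistic sensitivity analysis draws all uncertain parameters jointly
and independently — gamma for rates and costs (method of moments on mean
and SE), lognormal for hazard ratios (moments matched on the natural scale,
since SEs are reported on that scale), beta for utilities, uniform over
published min-max ranges — and re-runs all strategies per draw with common
random numbers. "± X%" utility variations are read as the half-width of a
95% interval (SE = half-range / 1.96); a direct-SE reading is available.
Fixture cost anchors receive a 20% relative SE. The full analysis uses
10,000 iterations; the packaged checks use smaller runs (200 iterations)
sized to keep the whole pipeline fast on one CPU. Iterations producing
non-finite output are flagged and excluded rather than aborting the run.

One-way (tornado) analysis moves each parameter to central ± 1.96 SE
(truncated to its support, or to the published range ends) and reports the
incremental net-monetary-benefit span of a chosen comparison, widest bars
first.

Scenarios are declarative overrides of the base configuration
(`scenario_specs()`): start at 30 or 35 (the horizon auto-extends to age
100 and the younger rate bands are picked up), 5/10-year constant surgical
disutility, 5-year chemoprevention effect, OC mortality × 0.70, deferred
reconstruction. Mixed uptake is a post-hoc weighted mean of per-strategy
totals, which is exact because the model is linear in cohort composition.

## Synthetic fixtures and what the tests show

The bundled life table is Gompertz-Makeham,
$q_x = 1-\exp\{-(A + B e^{\theta x})\}$ with $A=3\times10^{-4}$,
$B=1.2\times10^{-6}$, $\theta=0.13$, calibrated once so that disease-free
remaining life expectancy at 40 is about 45.5 years, matching a modern
Swiss female cohort; it reproduces the overall shape, not the year-by-year
detail, of a national table. With fixtures, the model reproduces the
published QALY and LY columns within ±5% for all five strategies in both
mutations and the published dominance pattern (the combined surgery is
cheapest and most effective; BRCA1 is costlier than BRCA2 under every
strategy). Absolute cost levels depend on the fixture anchors and are
regression-tested only directionally; reproducing the published cost column
requires transcribing the original tariff tables into the schedule file.

Validation in the test suite includes an independent individual-level
microsimulation (200,000 women on identical matrices, agreeing with the
cohort expectation within 3 standard errors), a geometric-series closed
form for the degenerate two-state model (1e-9), conservation of occupancy
under 200 random parameterizations (1e-10), a brute-force dominance oracle
over all strategy subsets, and method-of-moments checks of every PSA
sampler over 10^6 draws.

## Known limitations

* No ipsilateral BC recurrence (only contralateral), no direct DF-to-MBC
  transition, and no adverse events of Tamoxifen or surgery (endometrial
  cancer, thrombosis, cataract, perioperative mortality) — all excluded by
  design.
* Parameters are sampled independently in the PSA; no correlation structure
  is available.
* The life-table and cost fixtures are synthetic stand-ins; absolute cost
  outputs are watermarked and should not be quoted as Swiss tariffs.
* Compliance is embedded in the intention-to-treat effect sizes; no
  explicit adherence model.

## Worked example

```{r}
fit <- cua("BRCA1")
fit
summary(fit)
```
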