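---
title: "A societal-perspective Markov model of chronic idiopathic constipation treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A societal-perspective Markov model of chronic idiopathic constipation treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciccea)
```

## The model

`ciccea` compares three drugs for chronic idiopathic constipation (CIC) —
elobixibat 10 mg, linaclotide 0.5 mg and lubiprostone 48 µg — with a
deterministic Markov cohort model of four mutually exclusive health states:
the transient CIC entry state, *improved*, *unimproved* and *dead*. The entry
state exists only at time zero: it accrues nothing and is resolved
immediately by the responder split, so a cohort starting a drug with
responder proportion $p$ begins the first cycle with occupancy
$(p,\,1-p,\,0)$ over (improved, unimproved, dead).

Time advances in 28-day cycles over a 2-year horizon (26 cycles). Two flows
act per cycle: background mortality $m$ (annual 12.9 per 1000 converted to a
28-day probability, $m = 1-(1-0.0129)^{28/365} \approx 0.0010$) from both
alive states, and relapse $r$ (15% per year, $r \approx 0.0124$) from
improved to unimproved. No unimproved patient improves in the base case, and
nobody discontinues or switches.

Each cycle, alive occupants accrue:

* **medical costs** — the drug price in both states, plus disimpaction
  (every 12 weeks) and enema (every 2 weeks) in the unimproved state;
* **caregiving costs** — for the fraction aged ≥ 65 needing daily care,
  caregiver time on defecation management valued at the average wage;
* **productivity loss** — for the fraction under 65, overall work-impairment
  rates with and without controlled CIC times the average wage;
* **PAC-QoL** — the constipation-specific severity score (1.64 improved,
  1.88 unimproved; *higher is worse*). The accumulated, discounted score is
  divided by the number of cycles in the horizon; the divisor stays fixed,
  so deaths lower the score mechanically — which is why the mortality
  scenario is read jointly with the cost results.

Costs and QoL are discounted at 2% per year. The model also reports the
undiscounted expected number of cycles spent improved.

All inputs live in one YAML file; `base_case_params()` loads the shipped
base case, and every analysis is a pure function of a parameter object.

```{r}
params <- base_case_params()
run_base_case(params)[, c("arm", "total_cost", "d_total_cost", "qol_score", "d_qol")]
```

## Cycle and discounting conventions

Published cohort models rarely state their within-cycle bookkeeping, so the
two conventions that matter are explicit, config-selectable settings:

* `cycle_convention` (default `"mortality-first"`): deaths are resolved at
  the start of each cycle and survivors accrue that cycle's payoffs; relapse
  moves people at the cycle end. The alternative, `"accrue-first"`, accrues
  with the start-of-cycle distribution and applies all transitions
  afterwards. We ship mortality-first because it reproduces the published
  undiscounted cost components essentially exactly (medical and caregiving
  to within 1 JPY), whereas accrue-first sits about 0.1% high on every
  component.
* `discount_timing` (default `"cycle-end"`): cycle $t$'s accrual (0-based)
  is discounted by $(1.02)^{-(t+1)\cdot 28/365}$; `"cycle-start"` uses $t$
  cycle lengths. Cycle-end calibrates the discounted base case slightly
  better; both sit within a fraction of a percent of the published totals.

There is no half-cycle correction: the undiscounted results match the
no-correction geometric closed form, and the tests pin that identity. Under
mortality-first the expected improved duration has the closed form
$p\,(1-m)\sum_{t=0}^{25}\big[(1-m)(1-r)\big]^{t}$, because payoffs (and the
duration count) use the post-mortality occupancy.

`use_table1`-style rounding is also selectable: by default the engine uses
the full-precision per-cycle probabilities; `use_rounded_cycle_probs = TRUE`
switches to the 4-dp rounded values (0.0124, 0.0010). The difference is
below 0.01% everywhere.

A caveat a reader should know before comparing this model against the
published tables digit by digit: the printed per-arm durations are not
proportional to the responder proportions (13.273/0.6012458 = 22.076 but
9.476/0.4302036 = 22.027), which no deterministic cohort model can
reproduce — the published traces evidently carry a small Monte-Carlo
wobble, of the order of 0.1–0.3%. Totals and scores reproduce to ~0.05–0.2%
here; between-arm differences inherit the wobble of both endpoints and
should be compared on the scale of the totals, not of the difference.

## Responder proportions

The efficacy inputs are proportions achieving ≥ 3 spontaneous bowel
movements (SBMs) per week. They were originally obtained by sampling 1000
values from a normal distribution with the synthesized mean and SD of
network-meta-analysis results and counting the fraction at or above 3 (the
boundary is inclusive here; for a continuous distribution the choice is
measure-zero). `estimate_responder_proportion()` implements exactly that,
with any sample size and a mandatory seed, and `responder_closed_form()`
provides the analytic limit $1-\Phi\!\big((3-\mu)/\sigma\big)$ used as its
test oracle:

```{r}
responder_closed_form(3.5, 2)
estimate_responder_proportion(3.5, 2, n_samples = 1000, seed = 1)
```

The shipped config pins the published proportions (0.6012458, 0.4302036,
0.5308396) rather than re-sampling, so downstream results are
deterministic; comparator proportions relate to the reference through risk
ratios (0.7155, 0.8829). The exact synthesized means/SDs behind 0.6012458
were never published, so the sampling path is exercised with synthetic
summaries from `generate_sbm_summaries()`, whose known truth allows recovery
tests. Note the printed linaclotide risk ratio is itself rounded: 0.6012458
× 0.7155 reproduces 0.4302036 only to ~1e-5, which bounds the precision any
reimplementation can claim for that product.

## Sensitivity analyses

**One-way (±20%).** `run_dsa()` perturbs one parameter group at a time —
each arm's efficacy, the QoL pair, the procedure costs, each arm's drug
cost, the productivity pair, the caregiving pair — matching the published
ten-row layout (`dsa_groups(per_scalar = TRUE)` gives one run per scalar
instead). Pure cost parameters enter the totals linearly, so lower/upper
runs are exactly symmetric about the base case and QoL perturbation scales
the score by exactly 0.8/1.2; both identities are tested. Probabilities
pushed above 1 are clamped with a warning.

One published irregularity is deliberately not reproduced: the
comparator-efficacy rows of the published one-way table are not centred on
their own base case, and the offset equals the drug-price difference versus
the reference arm times the discounted alive person-cycles — consistent
with those rows having been computed with the reference drug's price. This
package keeps each arm's own price, so its lubiprostone +20% cost delta
(≈ +2,000 JPY) differs from the printed −20,364 while matching the printed
QoL delta (−0.007) exactly.

**Probabilistic.** `run_psa()` draws all uncertain inputs jointly: beta for
probabilities (moment-matched), gamma for unit costs, normal for the QoL
scores, lognormal for the risk ratios, each with a 10% coefficient of
variation where no standard error is available. The original distribution
assignments live in an unavailable supplement, so this assignment is a
conventional default and fully replaceable through the `distributions`
argument; the published quadrant percentages (72.3%/64.0% better QoL, etc.)
are therefore reproduced only qualitatively — the tests assert the
structural properties (coherent quadrants, seed stability within binomial
error, degenerate draws recovering the base case, reference-arm QoL
dominance above 50%) rather than those percentages. Parameters shared
between arms (transition probabilities, QoL, non-drug costs) use common
random values per draw; comparator efficacy scales the pinned proportion by
the relative movement of the sampled reference proportion and risk ratio.
Sampling is parameter-major under one master seed, so adding arms does not
reshuffle draws. `ce_plane_summary()` reports quadrant proportions (better
QoL means strictly *lower* PAC-QoL) and equal-tailed 95% intervals of the
cost and QoL differences.

## Scenario analyses

`apply_scenario()` expresses each published scenario as a declarative
modification of the base case; the base object is never mutated.

1. **Add-on laxatives.** Patients unimproved for 3 cycles receive stimulant
   (186.4 JPY/cycle) and osmotic (365.4 JPY/cycle) laxatives and gain a 4%
   unimproved-to-improved probability. This needs tunnel states — the
   memoryless engine cannot see time-in-state — so the unimproved state is
   expanded into stages (1st, 2nd, ≥ 3rd unimproved cycle) when, and only
   when, the add-on block is enabled; with it disabled the code path is the
   base engine, bit-identical. Two conventions were genuinely open. The 4%
   rate's time unit is unstated in the source (the study it cites is
   equally ambiguous); read per cycle it reproduces the published add-on
   cost columns to 0.4% and the QoL to 0.002, read per year it misses
   totals by ~7%, so per-cycle is the default
   (`improvement_time_unit = "year"` converts). And the published total
   cost column excludes the add-on drug costs themselves (the printed
   deltas only balance under separate accounting), so `total_cost` keeps
   the base cost structure and the add-ons are reported as their own
   columns.
2. **Discount rate** 0% or 3% (`option` is the rate).
3. **Unimproved mortality** ×1.19.
4. **Horizon** 5 or 10 years (65 or 130 cycles; the QoL divisor follows).
5. **Alternative impairment rates** 25.29%/35.54%, re-derived through the
   same productivity formula.
6. **No caregiving burden** — the only scenario touching derived costs
   directly; its totals equal base totals minus the base caregiving
   component exactly, a tested identity.

## Validation

Three independent oracles back the engine:

* `microsim_oracle()` — an individual-level simulation of up to 200,000
  patients with per-cycle Bernoulli death/relapse draws under the same
  accrual convention. It returns Monte-Carlo standard errors, and the test
  suite requires agreement with the cohort model within 3 SE for costs, QoL
  and duration (it converges at the expected $1/\sqrt{n}$ rate).
* Closed forms — the geometric-series duration, the person-cycle-weighted
  QoL identity, and degenerate regimes (stationary cohort, overwhelming
  mortality, no transitions).
* Structural invariants — occupancy rows summing to 1 within 1e-12,
  monotone death occupancy, non-increasing improved occupancy, exact
  component additivity, arm-order invariance, and YAML round-trip equality.

The synthetic generators define what the tests can and cannot show: they
emulate normal SBM outcomes, multiplicatively jittered parameter sets and
idealized cohorts. They do not emulate real-world heterogeneity, adverse
events, discontinuation, or drug-specific transition structure, so passing
tests demonstrate the model computes its stated quantities correctly — not
that the stated model is the right description of CIC care.

Problem sizes used by the shipped test suite: 26–130 cycles, microsimulation
at 50,000 (unit) and 200,000 (validation) patients, PSA at 200–2,000 draws
in tests (the published analysis used 10,000; `run_psa()` defaults to that),
responder-sampler checks at 10^5 draws.

## Known limitations

* Between-arm deltas are reproducible only to the noise floor of the
  published per-arm traces (~0.1–0.3% of the totals; see above).
* PAC-QoL is a severity score, not a utility; no QALYs or ICERs are
  computed, and no mapping to generic utilities is attempted.
* No adverse-event, tolerability or treatment-switching structure.
* The PSA's distribution hyperparameters are a documented convention, not
  the original assignment.
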