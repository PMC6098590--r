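---
title: "Modelling weekly patient access to therapeutic oxytocin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling weekly patient access to therapeutic oxytocin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxyaccess)
```

## The problem

Postpartum hemorrhage (PPH) is a leading cause of maternal death in
low-income settings, and therapeutic oxytocin is the frontline uterotonic
for preventing and treating it. Whether a woman actually receives a viable
dose at delivery depends on two coupled systems: the *supply side* — how
many doses arrive, how often, and how much potency they lose in storage —
and the *demand side* — how many women deliver at a facility at all, which
is shaped by wealth, literacy and distance. `oxyaccess` implements a
deterministic weekly system-dynamics model of this coupling for a small
island health system (Zanzibar is the reference setting), built around a
single headline output, the **weekly access ratio**:

$$
\mathrm{AR}_w \;=\;
\frac{\text{effective doses in stock in week } w}
     {\text{weekly demand} \times \text{weeks until the next shipment}}
$$

with the current week counted in the horizon. The denominator is the demand
the current stock must cover until it is replenished, so a ratio of 1.0
means supply exactly meets demand; the ratio is deliberately uncapped, so
oversupply is visible as values above 1. A year is 52 weeks and the
*average access ratio* is the arithmetic mean of the 52 weekly ratios.

## Degradation kinetics

Oxytocin in solution at pH 4.5 (its most stable formulation) degrades by
first-order kinetics with an Arrhenius rate constant

$$ k(T) = A \, e^{-E_a / (R T)}, $$

in units of day⁻¹ with $T$ in kelvin. The published kinetic constants
behind the reference stability data are not printed; instead the model
calibrates $(A, E_a)$ exactly through two quarter-year (91-day) stability
anchors: 80% of strength remaining at 35 °C and 20% at 45 °C. The per-day
rate at each anchor is $k = -\ln(f)/91$, giving

```{r}
kp <- calibrate_kinetics()
kp
```

Two further quarter-decay figures are quoted for the same data — just below
90% at 30 °C and 60% at 40 °C — but the four do not lie on any single
Arrhenius curve, so no two-parameter calibration can hit all of them. The
two outer anchors were chosen because they bracket the temperature range
that matters (the collapse above the critical ~30 °C region); the 30 °C and
40 °C figures are then treated as consistency checks with a ±6 percentage
point band, which the calibration meets (92.4% and 54.4%):

```{r}
remaining_strength(1, c(30, 35, 40, 45), 91, kp)
```

Decay integration defaults to the exact closed form
$s(t) = s_0 e^{-k t}$. A `"discrete-linear"` mode applying the
rate-times-interval update $s \leftarrow s (1 - 7k)$ once per week (floored
at zero) is provided as an alternative reading of weekly bookkeeping; for
$7k < 0.1$ it agrees with the closed form to within $(7k)^2/2$ per step and
is never the default, because the underlying process is explicitly
first-order.

Degraded stock is converted to *effective doses* by a band rule: full
credit at ≥ 85% strength, two vials per patient at 54–85% (half credit),
three at 33–54% (one-third credit), and zero below 33%, where stock is
written off as non-viable. The published band edges overlap (50–85% and
33–54% both contain 50–54%); the bands here are half-open with the 54%
boundary kept — $[0.85, 1]$, $[0.54, 0.85)$, $[0.33, 0.54)$,
$[0, 0.33)$ — because that is the only choice of printed edges that
partitions $[0,1]$. Divided counts are floored: doses are physical vials.

## Access and demand

Three covariates carry the published facility-delivery odds ratios: richest
wealth quintile 2.55, literacy 1.99, rural residence 0.82. Odds ratios
alone do not define a probability, and the published endpoints (41%
facility delivery for a fully illiterate population, 53% for a fully
literate one, ≈ 50% at the actual 67% literacy) cannot be recovered from
any obvious logistic construction, so the package offers two forms and is
explicit about which is which:

* **anchored_linear** (default): the literacy response is pinned exactly to
  the printed endpoints, $p = 0.41 + 0.12 \times \text{literacy}$, with
  departures of the richest-quintile and rural shares from their defaults
  applied as log-odds perturbations using their odds ratios. This mode is
  used for reproduction of the published numbers.
* **logistic**: the population is split into the eight richest × literate ×
  rural cells with independent composition; each cell gets
  $\mathrm{logit}^{-1}(\beta_0 + \sum \ln(\mathrm{OR}_i) x_i)$ and the
  marginal is the share-weighted mean. $\beta_0$ is calibrated by monotone
  root-finding so the marginal hits a known figure (50% here), giving
  $\beta_0 \approx -0.545$ at the default composition. Its literacy
  endpoints then land at 39.0% and 55.4%, within 5 points of the printed
  ones — a useful check that the two constructions tell the same story.

Distance enters only through the rural/non-rural odds ratio (0.82), the
model's distance proxy: `distance_scenario()` reclassifies a share of the
population from rural to within-5-km and re-evaluates the probability. No
continuous distance-decay function is introduced, because none is
published; a consequence the model reproduces is that doubling the
within-5-km share from 50% to 100% raises access by under 5 percentage
points in both modes.

Weekly demand is the expected value
$\frac{\text{annual births}}{52} \times p_\text{access} \times
(1 + 0.02 \times 4)$ — one prophylactic dose per facility birth plus a 2%
PPH incidence requiring four additional doses, i.e. 1.08 doses per facility
birth. Demand is deliberately not sampled: the model treats demand as the
same every week, so all results are deterministic and the simulator needs
no random numbers outside fixture generation.

The default of 49,074 annual births is a *derived* constant: the published
full-access requirement of 53,000 doses/yr divided by the 1.08 multiplier.
All such defaults live in one table, `oxy_defaults()`.

## The inventory engine

The year runs on a 0-based weekly clock (reports label weeks 1–52). The
annual order arrives in equal shipments at equally spaced weeks
(`floor(52 i / n)`, so semiannual shipments land at weeks 0 and 26,
quarterly at 0, 13, 26, 39). Each week, in order:

1. an arriving shipment joins the inventory as a new cohort at full
   strength;
2. every cohort decays by 7 days at the week's temperature;
3. effective doses are computed per cohort with the band rule and summed;
4. demand, rounded **up** to whole patient doses at this step only, is
   served FIFO — each patient draws 1, 2 or 3 physical vials according to
   the serving cohort's band, atomically from one cohort, with a patient
   straddling a stock-out of one cohort completed from the next at that
   cohort's own multiplier;
5. cohorts below 33% strength are written off;
6. the weekly access ratio is recorded from the *post-decay,
   pre-consumption* effective stock.

Recording post-decay, pre-consumption with the current week counted in the
forward horizon is the only reading that produces the characteristic
sawtooth — a trough in the week immediately before each arrival and a jump
at the restock week. Dose accounting is exact by construction: every
supplied vial is consumed, written off, or carried over at year end, and
the test suite asserts this integer conservation on every simulated
configuration.

Two engine properties worth stating precisely, because plausible-sounding
stronger claims are false:

* Consumption is demand-limited, so post-consumption stock is *affine*,
  not proportional, in the annual order: doubling supply does not double
  each weekly ratio, but equal supply increments produce equal ratio
  increments while no shortfall or band transition occurs (tested).
* At deep shortfall the ratio has a flat zero tail at the end of each
  cycle, so "the trough is the week before the shipment" holds in the weak
  sense there; near balance it holds strictly.

`minimal_supply()` searches the annual order for the smallest supply whose
average access ratio reaches a target. Because doses are integers the
average ratio is a step function of the order size, so the search runs
bisection on an integer bracket until it collapses — a fixed-point
tolerance on the ratio itself cannot terminate reliably — and reports the
result rounded to the nearest 100 doses, the precision at which
requirements are quoted. At cold-chain temperatures (≤ 25 °C no band
transition occurs all year) the search agrees with the closed-form balance
`52 × weekly demand` to within consumption rounding, which is the
cross-check the tests freeze.

## Scenario projection

Multi-year projections re-run the full weekly engine each year rather than
scaling year-0 output, so temperature–band interactions are respected.
Births compound at 3%/yr by default; a family-planning intervention
subtracts its stated percentage points from the growth rate *cumulatively*
each intervention year (the only reading that produces large long-run
effects; a one-time reduction mode is also provided), and literacy
campaigns add percentage points per year until saturation at 100%.
`required_supply_trajectory()` gives the per-year order needed to hold the
average ratio at 1; `access_decline_trajectory()` holds the order fixed
and watches the ratio fall.

One scaling intuition deserves a caution: with a fixed order and growing
demand, the average ratio does **not** fall exactly as
$1/(1+g)^y$. Consumption reshapes the stock path as demand grows (stock
runs out earlier in each cycle), so the decline is faster than pure
$1/\text{demand}$ scaling. The tests therefore assert the robust
qualitative properties — the series is flat at zero growth and strictly
decreasing under positive growth — rather than a closed form that the
engine's own semantics contradict.

`loss_fraction()` closes the loop on procurement: comparing the
100,000-dose national order with the ~26,500-dose modelled requirement at
50% access implies 73.5% of the supply never reaches a patient.

## Numerical choices and scale

* All simulations here are desk-scale: one year is 52 weekly steps over at
  most a handful of cohorts, a `minimal_supply()` search is ~20
  simulations, and the 31-year projection used in the tests re-runs the
  search each year in a few seconds.
* The brute-force cross-check in the test suite re-implements the engine
  rules at day resolution (daily decay, per-patient FIFO service in a
  plain loop) and agrees with the weekly engine's average ratio within 2%
  on a 10-point grid over supply, shipment frequency, temperature and
  access.
* Temperature profiles are step functions of week; the last value extends
  to cover any horizon. The synthetic seasonal fixture is a sinusoid
  (mean, amplitude, 52-week period) plus optional Gaussian noise under a
  fixed seed — it emulates a smooth annual ambient cycle and deliberately
  not short hot excursions, cold-chain breaks in transit, or intra-week
  spikes, so passing tests say nothing about those regimes.
* Week indexing is 0-based internally and 1-based in reports; published
  figures mix both conventions, which is why a semiannual peak can be
  quoted at "week 25" and a quarterly arrival at "week 14".

## What the model leaves out

By design (following the source model's own assumptions): no shipment
delays or lead-time variability, no light- or agitation-driven decay, no
pH other than 4.5, no private-donor supply, no transit between the central
store and individual facilities, no facility-level disaggregation, no
monetary costing, and no cultural determinants of facility delivery. The
published pairing of a 25,500-dose order with an average ratio of 0.85 is
not reproducible under any linear reading of the access-ratio definition
(25,500/26,500 ≈ 0.96) and is not targeted. Demand determinism also means
the model says nothing about stochastic stock-outs caused by weekly demand
variance; its stock-outs are purely structural (cycle timing, decay, and
under-ordering).
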