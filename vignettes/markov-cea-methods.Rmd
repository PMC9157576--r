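---
title: "Methods: a two-state Markov cohort model for supplemental home parenteral nutrition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-state Markov cohort model for supplemental home parenteral nutrition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpncea)
```

## The decision problem

Malnourished patients with incurable gastrointestinal cancer can receive
supplemental home parenteral nutrition (sHPN) — intravenous feeding at home
covering a quarter to a third of daily needs — on top of dietetic
counselling, or best-practice nutritional care alone. sHPN improves quality
of life and muscle status but adds drug, catheter, and nursing costs. The
package asks whether, from the Chinese healthcare perspective, the extra
cost buys enough extra quality-adjusted survival: the incremental
cost-effectiveness ratio (ICER) is compared with a willingness-to-pay (WTP)
threshold of three times per-capita GDP, $29,307 per QALY.

## Model structure

The model is a cohort-level state-transition (Markov) model with two health
states, *alive* and *dead*, a 6-week (42-day) cycle, and a 5-year horizon
(43 cycles, `floor(5 * 365.25 / 42)`). Survival in each arm follows a
Weibull law $S(t) = \exp(-\lambda t^{\gamma})$, so the probability of dying
during the cycle that ends at time $t$, conditional on being alive at its
start, is

$$P_t \;=\; 1 - \exp\!\left[\lambda (t-u)^{\gamma} - \lambda t^{\gamma}\right]
       \;=\; 1 - \frac{S(t)}{S(t-u)},$$

with $u$ the cycle length in the survival model's time units. Because the
per-cycle survivors multiply, the alive fraction at the start of cycle $k$
is exactly $S(ku)$ (the telescoping identity the test suite checks to
1e-12). With $\gamma = 1$ the hazard is constant and $P_t$ collapses to the
memoryless $1 - e^{-\lambda u}$.

`fit_weibull()` estimates $(\gamma, \lambda)$ from digitized Kaplan–Meier
coordinates by ordinary least squares of $\log(-\log S)$ on $\log t$
(complementary log-log linearization; slope $\gamma$, intercept
$\log\lambda$). This is the right estimator for curve *coordinates*: the
individual event times behind a published figure are unavailable, so a
censored-data likelihood has nothing to bind to, while the linearization is
exact on noiseless Weibull points. Points with $S \ge 1$ (including the
$t=0$ anchor) or $S \le 0$ are excluded, not clamped, and reported.

## Accrual conventions

Costs enter as items that recur each cycle or are incurred once. One-time
items at model entry are counted at full cohort weight, undiscounted.
Per-cycle items accrue in every cycle of their applicability window,
weighted by the alive fraction *at cycle start* and discounted at 3% a year
pro-rated by exact day count, $(1+r)^{-k \cdot 42/365.25}$ — identically
for costs and QALYs. There is no half-cycle correction in the reference
convention (a `half_cycle` switch exists for sensitivity); cycle-start
weighting plus visit-end utilities is the convention that reproduces the
published per-visit incremental costs to within 0.3%.

QALYs: cycle $k$ contributes
$\text{alive}_k \times \text{utility}(k) \times 42/365.25 \times \text{discount}(k)$.
Utilities are measured at visits 2–5, which fall at the *ends* of cycles
0–3; the reference mapping therefore assigns cycle $k$ the visit-$(k{+}2)$
utility and carries the visit-5 value forward, on the view that the
measured utilities describe on-treatment states while the baseline utility
describes the pre-model state and is never accrued. The alternative
mapping (cycle $k$ → visit $k{+}1$, starting from baseline) is available
via `utility_mapping = "visit_k1"`.

### The under-specified conventions, made explicit

Two published choices cannot be recovered from the parameter table alone:

* **The time unit of shape and scale.** The printed $(\gamma, \lambda)$
  pairs imply a median survival of about 17 *model units* per arm, but the
  reported medians are 168 and 169 *days* — no natural unit (days, weeks,
  cycles) reconciles the two. `weibull_survival()` therefore exposes
  `time_unit_days`, and `calibrate_median()` can rescale $\lambda$ to a
  stated median without guessing the original convention.
* **Whether treatment-linked per-cycle costs stop at 24 weeks.** The
  parenteral-nutrition, catheter-care and homecare-nurse items are labelled
  per-cycle with no end date, yet treatment lasted 24 weeks (4 cycles).
  `with_treatment_window()` expresses either reading through the cost
  items' applicability windows.

`explore_conventions()` runs the base case over the grid
`time_unit_days` $\in \{7, 14, 42\}$ × treatment window $\in \{4, \infty\}$
cycles and ranks the combinations by their worst relative discrepancy
against supplied reference totals. On the packaged fixture the best
combination is a 14-day unit with the 24-week treatment window, which
brings all five primary quantities (both arms' costs and QALYs, and the
ICER) within ±20% of the published values; every unbounded-cost
combination is far outside that band. The package reports this
configuration rather than asserting it was the authors' choice.

## Outcomes

`compute_icer()` forms $\Delta C$, $\Delta E$, the ICER
$\Delta C/\Delta E$, and a dominance class (dominant / dominated /
trade-off by quadrant); the ICER is only meaningful in the trade-off
quadrants, and negative ratios are passed through numerically but flagged
by their class. `nmb()` is the linear decision rule
$\text{WTP}\cdot\Delta E - \Delta C$, and `headroom()` — the same quantity
read as money — is the largest extra one-time intervention cost (e.g. a
catheter-care training fee) that keeps the ICER at or below the threshold.

Secondary ICERs re-use the machinery with a different effect axis: for each
metric (quality of life, BMI, fat-free mass, FFM index, handgrip, 6-minute
walk) and visit $v$, $\Delta E_v$ is the between-arm difference in change
from baseline, and $\Delta C_v$ is the between-arm difference in
per-patient discounted cost accumulated over cycles $0..v{-}2$ at *full*
cohort weight (`cost_through_visit()`). Full weight — rather than the
trace's alive-weighting — is deliberate: the metrics are measured on
patients alive at the visit, so the matching cost is what a surviving
patient has accumulated. This convention reproduces the published
quality-of-life ICERs at visits 2–5 to within 0.6%, where alive-weighting
drifts to ~3% by visit 3. Units ride along on every result so $/kg and
$/m can never be compared silently.

## Sensitivity analyses

**One-way (tornado).** Each cost item is varied ±50%; each arm's utility
schedule and each arm's Weibull (shape, scale) pair are varied as grouped
±30% multipliers (keeping cycle-to-cycle coherence — perturbing each
per-cycle $P_t$ independently would break the survival curve). A cost item
appearing in both arms with the same amount is one *shared* parameter
varied jointly, so its influence flows only through the arms' differing
survival weighting and vanishes when the traces coincide. Entries carry the
ICER at both ends, but ranking uses the spread in net monetary benefit at
the model's WTP: across a range in which $\Delta E$ changes sign the ICER
passes through a pole, so its spread is not a usable influence measure,
while NMB is linear in the increments. On the fixture this ranks the sHPN
utilities first — the qualitative finding of the original analysis, which
the ICER-spread definition would not reproduce.

**Probabilistic.** Utilities and the Weibull shape/scale (all in $(0,1)$
here) are drawn from beta distributions, costs from gamma distributions,
each moment-matched to mean $m$ and standard deviation $m f / 1.96$: the
deterministic band $m(1 \pm f)$ is read as a central 95% interval, a common
convention when a source states ranges but not distributional parameters
(`interval_interpretation = "two_sd"` gives the $m f/2$ alternative). A
mean outside $(0,1)$ where a beta is required raises an error rather than
silently switching family. One master seed draws a fixed vector of
per-iteration substream seeds, so the 1,000-iteration Monte Carlo is
bitwise reproducible and order-invariant. The CEAC reports, per WTP on a
default grid of $0–$60,000 by $500, the fraction of iterations with
positive NMB. Because all distributions are centred on the base-case
means, the PSA cannot — and the package does not try to — reproduce the
published claim of acceptability at $2,500/QALY, which sits far below the
base-case ICER; the CEAC value there is simply computed and reported.

## Synthetic data

`synthetic_trial_spec()` emulates the source trial's design: 24 + 23
patients, Weibull survival per arm (the packaged shapes with scale
calibrated so medians are 168/169 days), administrative censoring at the
24-week treatment window (a 5-year option exists for survival-tail work),
and per-visit effect trajectories as mean change from baseline plus
additive Gaussian noise. The quality-of-life means equal the fixture's
utility deltas, so the synthetic route reproduces the fixture's secondary
ICERs exactly at zero noise; the other metrics' means are plausible
trajectories chosen once (improvement under sHPN, slow decline under usual
care), since the trial reports no dispersions — the noise sds are defaults,
not estimates. Digitizer error is Gaussian on the survival axis only, with
exact time positions, mimicking pixel-reading error; jittered values are
clipped to $(0,1]$.

What the generator does *not* emulate: recruitment and dropout mechanisms,
patient-level cost variation (the model is cohort-level), correlation
between effect metrics, and non-Weibull survival shapes. Passing
parameter-recovery tests on this generator therefore shows the estimator
chain is consistent under the model's own assumptions, not that real
digitized curves are this well behaved.

## Numerical choices and test scale

Monetary inputs are validated to 2 decimals and carried at full double
precision; currency conversion (7.012 CNY/USD) happened upstream and is
metadata only. Telescoping and conservation are asserted to 1e-12. The
test suite's simulation sizes were chosen to keep the full run under half a
minute while leaving comfortable statistical margins: parameter recovery
uses 100–200 seeds at 500 patients/arm with 30–60 digitized points (median
relative errors ≤10–15%), moment checks use $10^5$ direct draws, PSA
mean-centring uses 1,000 iterations with 3-standard-error bounds, and the
end-to-end synthetic reproduction uses 4,000 patients/arm.

## Known limitations

* Two health states only: no progression, complication or tunnel states,
  and no individual-level microsimulation.
* The Weibull time-unit ambiguity is surfaced, not resolved; all primary
  reproductions are conditional on the convention search.
* Secondary metrics other than quality of life have no published
  change-from-baseline values, so their ICERs are only consistency-checked
  via back-calculated effects.
* No EVPI, no correlated parameter sampling (no correlation structure is
  given), and no utility mapping from instruments — utilities enter as
  numbers.
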