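---
title: "Markov cohort cost-utility analysis of dialysis modalities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov cohort cost-utility analysis of dialysis modalities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(renalcea)
```

## The decision problem and the model

`renalcea` compares strategies for allocating incident end-stage renal
disease patients between peritoneal dialysis (PD) and hemodialysis (HD). A
strategy is a starting mixture: a share `pd_share` of the cohort begins in
PD and the rest in HD. Patients then move annually between five states —
`PD`, `HD`, first transplant year `TX1`, later transplant years `TXP`, and
absorbing `DEAD` — under a single time-homogeneous transition matrix.

Three modelling assumptions deserve emphasis.

* **Tunnel state for the first transplant year.** Transplantation has a
  high first-year cost (surgery, induction immunosuppression) and a much
  lower maintenance cost afterwards. A memoryless chain cannot express
  "cost depends on time since transplant" in one state, so the transplant
  phase is split: everyone entering `TX1` leaves it after exactly one cycle
  (to `TXP`, back to dialysis on graft failure, or to `DEAD`). Both
  transplant states share one utility weight.
* **Time homogeneity.** One matrix drives all cycles. Age-dependent
  mortality and era effects are out of scope.
* **Rejection returns to dialysis, split 50/50.** Graft failure sends equal
  probability to HD and PD. This split is structural, not calibrated.

Discounted totals accrue from start-of-cycle occupancy: payoffs of cycle
*t* (occupancy row *t*, for *t* = 0..T−1) are weighted by (1+r)^(−t), so the
first year is undiscounted. This is the most common cohort convention; since
published reports rarely state theirs, `accumulate_payoffs()` exposes the
discount rate and a `half_cycle` flag (mean of start- and end-of-cycle
occupancy) so either convention can be reproduced. Half-cycle correction is
off by default.

## Parameters

| Parameter | Unit | Default | Why |
|---|---|---|---|
| per-state cost | million IRR / state-year | fixture: 1143.65 (PD), 848.86 (HD), 538.75 (TX1), 64.46 (TXP) | published direct medical costs for the Iranian setting |
| per-state utility | QALY weight in [−1, 1] | 0.550 (PD), 0.423 (HD), 0.695 (TX1/TXP) | published EQ-5D means |
| `discount_rate` | proportion / year | 0.035 | conventional health-economics rate, used by the reference analysis |
| `horizon` | years | 10 | reference analysis timeframe |
| `pd_share` | proportion | scenarios 0.03, 0.30, 0.50, 0.70 | 3% is current practice; the others are policy scenarios |
| transition knobs | annual probabilities | synthetic calibrated set | see below |
| `cost_cv` (PSA) | coefficient of variation | 0.2 | cost SDs are not published; 0.2 is a conventional PSA default, and results under it are this package's own, not a reproduction |
| `ess` (PSA) | Dirichlet effective sample size | 100 | moderate uncertainty on transition rows; configurable |
| `n_iterations` (PSA) | iterations | 1000 | matches the reference analysis's Monte Carlo size |
| `wtp` | million IRR / QALY | grid 0–6000; decision threshold 3000 | treated as a free parameter — published GDP-per-capita conversions for Iran are internally inconsistent, so no single "correct" λ is assumed |

## The synthetic transition parameters

The published analysis sources its transition probabilities (dialysis
survival, transplant incidence, graft failure) from literature and a claims
database without printing them. The package therefore treats them as six
annual-probability *knobs* (`transition_knobs()`): HD and PD mortality, a
dialysis-to-transplant rate, first- and later-year transplant mortality, and
rejection. Three ways to obtain them:

1. **Direct**: set them from your own sources.
2. **Random** (`random_knobs()`): uniform draws within plausible ranges
   (dialysis mortality 5–30%/yr, transplant incidence 0.5–15%/yr,
   post-transplant mortality and rejection 0.5–10%/yr), rejection-sampled to
   feasibility. These ranges bracket values typical of dialysis registries;
   they are deliberately wide because the draws exist to exercise the
   engine, not to estimate anything.
3. **Calibrated** (`calibrate_knobs()`): fit to published per-scenario
   discounted totals.

Calibration minimizes the sum of squared relative errors over all targets
with Nelder–Mead on logit-transformed knobs (so box constraints are
automatic), a large penalty for rows whose exits exceed 1, a tight
`reltol` (1e−14) and one restart from the first optimum to escape simplex
stalls. It is deterministic for a fixed start.

One design choice was forced by the arithmetic. Because the cohort model is
exactly linear in the starting mixture, the four scenario targets contain
only four independent quantities: pure-HD and pure-PD cohort cost and QALYs.
A *shared* dialysis-to-transplant rate cannot hit all four — it ties the HD
and PD cost/QALY margins together, and the best shared-rate fit (≈0.46% per
target) badly distorts the cost and QALY *slopes* between scenarios, i.e.
exactly the increments and ICERs the analysis reports. Freeing a
modality-specific PD transplant rate (`pd_to_tx`, the default
`share_tx = FALSE`) fits all eight targets to ~10⁻⁵ relative error with
plausible values. `synthetic_calibrated_knobs()` freezes that solution
(rounded to six decimals) as the fixture default; it reproduces every
published total at its printed precision. Because seven knobs fit four
quantities, the knob vector itself is *not identified* — only the outputs
are. The calibrated set is a plausible point in a solution manifold and is
labelled synthetic wherever it is serialized.

A related display subtlety: published tables round totals before printing
but compute increments from unrounded values (the printed 2268.2 vs 2266.7
ICER wobble is pure rounding of an exactly collinear frontier). The
package's display convention mirrors this — full precision internally,
costs to 1 decimal, QALYs to 4, ICERs to 1 for display.

## Probabilistic sensitivity analysis

Per iteration, one joint parameter draw rebuilds the model and evaluates
*all* scenarios (common random parameters — without this, scenario
differences would be noise-dominated and the CEAC meaningless):

* **Costs** — gamma, moment-matched (`shape = (mean/sd)²`,
  `scale = sd²/mean`) at `cost_cv`.
* **Utilities** — beta, matched to the *standard error* of the published
  mean (SD/√n with n = 76 PD, 312 HD, 130 transplant). The published
  patient-level SDs are infeasible for a beta at the published means
  (e.g. mean 0.423, SD 0.549), and parameter uncertainty about a cohort
  mean is the quantity a PSA should propagate. `beta_from_moments()`
  records the fallback whenever it fires. The beta family lives on [0, 1],
  so utilities worse than death are truncated at zero by construction.
* **Transition rows** — Dirichlet with concentrations `ess × p`, keeping
  rows stochastic and structural zeros (including the `TX1` tunnel) exactly
  zero, rather than independent betas renormalized ad hoc.

Ties in the per-iteration NMB comparison go to the cheaper scenario (then
input order), so CEAC probabilities always partition the iterations. Any
draw that fails matrix validation is rejected, redrawn and counted; with
Dirichlet rows this is essentially never exercised.

## Numerical choices

* Row-stochasticity: deviations ≤ 1e−6 are renormalized with a warning
  (and entries clamped to [0, 1]); larger deviations are errors naming the
  row. Validated rows sum to 1 within 1e−9.
* Extended dominance drops a strategy only when its sequential ICER exceeds
  the next step's by more than 1e−8 relative — exactly collinear mixtures
  stay on the frontier despite floating-point noise.
* `icer()` never divides by a zero QALY difference; it returns dominance or
  undefined verdicts instead.
* Degenerate inputs: duplicate scenario names, empty WTP grids, infeasible
  knob combinations, and calibration target sets with fewer than two
  distinct shares are all rejected with specific errors.

## What the generator and tests do and do not show

The synthetic machinery emulates the *structure* of the decision problem —
a homogeneous five-state chain with the published payoffs and plausible
transition magnitudes. It does not emulate age- or vintage-dependent
hazards, modality switching on dialysis, waitlist dynamics, correlated
parameter uncertainty, or costs that trend over time. Passing tests
therefore certify the engine's arithmetic (conservation, linearity,
monotone mortality, agreement with a 200,000-patient microsimulation within
Monte Carlo error), the published-value arithmetic that *is* reproducible
(ICERs, mixture linearity, calibration to totals), and the internal
consistency of the PSA — not the clinical accuracy of any particular knob
value, nor PSA proportions that depend on unpublished cost variances.

Problem sizes used throughout (chosen to pin Monte Carlo error well below
the effects being checked): 1000 PSA iterations, 200,000 microsimulation
patients in the engine check (40,000 in the quicker unit test), 10⁶ draws
in the distribution round-trip checks.

## Worked example

```{r example, eval = FALSE}
fix <- esrd_fixture()
results <- run_scenarios(fix$model, fix$scenarios)
cea_table(results)
decide(results, wtp = 3000)

spec <- default_psa_spec(fix$model, n_iterations = 1000, seed = 1)
psa <- run_psa(fix$model, fix$scenarios, spec)
autoplot(ceac(psa, seq(0, 6000, by = 200)))
```

## Known limitations

* One transition matrix for the whole horizon; no age structure or
  secular trends.
* The calibrated knobs are output-identified only; do not interpret them as
  estimates of Iranian dialysis epidemiology.
* PSA proportions depend on the assumed `cost_cv` and `ess`; both are
  conventions, clearly surfaced in the spec objects, not estimates.
* The model is linear in `pd_share` by construction, so intermediate
  mixtures can never strictly dominate the corners; policy questions about
  capacity constraints or transition costs of scaling PD are out of scope.
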