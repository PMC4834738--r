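---
title: "Methods: the energy-balance model and adherence engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the energy-balance model and adherence engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weightrx)
```

weightrx implements the quantitative core of a remote weight-management
program: predict what a client's weight *should* do under an
energy-intake prescription, compare what it *actually* does, and act on
the difference. This vignette documents the model, the tunable
parameters, the operationalizations chosen where the underlying program
rules are qualitative, and the known limitations.

## The two-compartment energy-balance model

Body weight is modeled as fat mass $F$ and fat-free mass $L$ (kg), with
constant tissue energy densities $\rho_F = 9440$ and $\rho_L = 1816$
kcal/kg. An energy imbalance $I - E$ (intake minus expenditure,
kcal/day) is partitioned between the compartments by a Forbes-type rule:

$$\rho_L \frac{dL}{dt} = p(F)\,(I - E), \qquad
  \rho_F \frac{dF}{dt} = (1 - p(F))\,(I - E), \qquad
  p(F) = \frac{C}{C + F},$$

with $C = 10.4\,\rho_L/\rho_F \approx 2.0$ kg. This $p$ is exactly the
derivative of the empirical cross-sectional body-composition curve
$L = 10.4 \log F + b_{sex}$, so a trajectory that starts on the curve
stays on it — which also makes re-initializing the model from any
later observed weight self-consistent (used by the intake estimator).
Baseline composition is obtained by inverting the same curve at the
enrollment weight. The female intercept 14.2 kg is the classical
curve; the male intercept default of 23.2 kg is the package's own
calibration (giving roughly 25–30 % body fat for typical middle-aged
men) and, like every constant here, is overridable via `model_params()`.

Expenditure combines a sex-specific linear resting-metabolic-rate
regression on weight, height and age (the Mifflin–St Jeor
coefficients), a physical-activity multiplier, the thermic effect of
feeding, and a metabolic-compensation term proportional to weight
change from baseline:

$$E = \mathrm{PAL} \cdot \mathrm{RMR}(W) + \beta I + \eta\,(W - W_0),$$

with defaults $\mathrm{PAL} = 1.5$ (light-to-moderate activity, about
150 min/week — the only activity regime the model claims validity
for), $\beta = 0.10$, and $\eta = 37.3$ kcal/day per kg. Maintenance
intake solves $I = E$ at baseline: $I_m = \mathrm{PAL}\cdot
\mathrm{RMR}(W_0)/(1-\beta)$.

**Calibration.** $\eta$ is the single calibrated constant. It was
chosen (once, by root-finding) so that the package's reference
scenario — a 50-year-old woman, 65 in, 200 lb, reducing intake by
500 kcal/day — loses 17.4 lb (8.7 %) over 12 months, matching the
published behavior of validated energy-balance weight-loss predictors
for exactly this input. Qualitatively $\eta$ aggregates everything
that shrinks the deficit as weight falls beyond the RMR decline
(adaptive thermogenesis, reduced cost of moving a lighter body, and
behavioral drift); its value is at the high end of what metabolic-ward
studies report, which is what reproduces the comparatively conservative
12-month prediction.

The system is integrated with `deSolve::lsoda` (adaptive, tolerances
$10^{-9}$) on a daily output grid, block-wise across intake
discontinuities so the solver never steps over a jump. A third state
accumulates $\int (I-E)\,dt$ so energy bookkeeping can be asserted
exactly; the test suite also checks the solution against an
independent fixed-step Euler integration at 0.01-day steps (agreement
is ~$10^{-4}$ kg over a year). Intake changes are modeled as
instantaneous steps, not ramps.

```{r fig1}
prof <- client_profile("female", 50, height_in = 65, weight_lb = 200)
rx <- energy_prescription(maintenance_energy(prof), -500, 365)
tr <- predict_trajectory(prof, rx)
c(maintenance = maintenance_energy(prof),
  loss_lb = tr$weight_lb[1] - tr$weight_lb[366])
```

## Estimating intake from observed weights

`estimate_intake()` inverts the forward model: the day grid is cut
into consecutive non-overlapping windows (default 14 days; 28 days
roughly halves the noise), and within each window a one-dimensional
bounded minimization (`stats::optimize`) finds the constant intake
whose simulated weights best fit the retained observations in least
squares. Two design points matter:

* **State is carried, not re-anchored.** Window 1 starts from the
  enrollment baseline composition (a known, noise-free state); each
  later window starts from the previous window's fitted end state.
  Anchoring each window at its first *observation* would let a single
  0.3 kg scale error masquerade as ~±150 kcal/day; carrying the model
  state keeps the estimator's standard deviation near the
  information-theoretic floor (≈30 kcal/day for a 28-day window at
  0.3 kg daily noise).
* **Gaps.** Windows with fewer than two observations are skipped and
  flagged, and the state coasts through them at the last fitted intake
  (maintenance before any fit).

Noise-free weights are recovered to within the optimizer tolerance
(±5 kcal/day); at 0.3 kg daily noise a single 28-day window recovers a
−500 kcal/day deficit with ≈26 kcal/day mean absolute error.

## Telemetry cleaning

Raw records (device pushes or manual entries, CSV or JSON) pass two
rules, both auditable in the output (`excluded` column):

1. **First of day** — the earliest record per calendar date is
   retained; later ones are marked `duplicate_same_day`. A config
   switch keeps all records for within-day fluctuation studies.
2. **±5 % filter** — scanning retained records in date order, a weight
   deviating from the last *retained* weight by strictly more than 5 %
   is marked `outlier_gt_5pct` and does not move the reference, so a
   run of foreign weights (another person on the scale) cannot poison
   later comparisons. Exactly 5 % is kept. Manual entries are cleaned
   identically to device entries, for auditability.

Limitation: the first observation is always retained, so a foreign
weight on day 0 inverts the filter's verdicts until the true client
weighs in within 5 % of the impostor — visible as reduced filter
accuracy in the contaminated-stream summary the acceptance script
reports.

## The zone of adherence and daily flags

The zone is a band around the predicted trajectory; the default is
symmetric ±2 % of baseline weight (configurable as absolute lb/kg or
asymmetric). Each client-date receives exactly one flag:

| flag | rule |
|------|------|
| `GREEN` | in zone, neither plateau nor near-edge condition |
| `GREEN_YELLOW` | in zone, but plateauing while the prediction slopes down, or in the top 20 % of the band |
| `RED` | out of zone (above without an adherent trend, or below) |
| `RED_GREEN` | above zone but trailing slope ≤ predicted slope (on course to re-enter) |
| `NO_DATA` | no retained weight |

Trailing slopes are least-squares fits over the last 7 days of
retained weights (at least 3 points; with fewer, only the in/out test
applies). **Plateau operationalization:** daily weights at realistic
noise (sd ≈ 0.3 kg) make the raw condition "7-day slope ≥ 0" fire on
15–40 % of genuinely adherent days, because the slope estimator's sd
(≈0.057 kg/day) dwarfs true loss rates (0.02–0.06 kg/day). The package
therefore declares a plateau only when the slope is non-negative with
one-sided 95 % confidence (a t-test using the fit's own residual
error). For noise-free series the residual error is zero and the rule
reduces to the raw slope ≥ 0 test, so deterministic fixtures behave
literally. `flag_config(plateau_conf = NULL)` restores the raw rule.

The k-of-n trigger (default 3 of 5) fires when enough of the most
recent dated flags are `RED`. `RED_GREEN` signals recovering adherence
and is excluded by default (configurable); `NO_DATA` days occupy
window slots but never count toward k. With fewer than n dated days
since enrollment the trigger never fires.

## Activity, toolbox, tips, feedback, reports

Step goals are baseline + increment (default 3000; a 4000-step
baseline yields the canonical 7000–8000 steps/day), compared daily
against the maximum of same-day cumulative syncs — steps, never kcal,
are the goal currency. The toolbox escalates least-intense-first
within an "escalation run" (episodes since the last success; a success
resets to the cheapest remedy — a new lapse is a fresh problem), with
a 14-day evaluation window per episode: success means back in zone on
the last observed day *or* an episode slope at least as steep as
predicted; fewer than 3 weights defer the evaluation and extend the
episode. Tips are scheduled per phase (weekly, tapering to biweekly
and monthly); feedback events are template-based and deterministic,
each carrying its trigger provenance; reports (usage, outcome,
toolbox, group) count only retained observations, display percentages
half-up to one decimal, and count enrollment days inclusively.

## The synthetic-client generator

`simulate_client()` produces telemetry whose ground truth is known:
the true weight follows the forward model at effective intake
$I_m + a\,\Delta$ (adherence fraction $a$, plus optional lapse
windows), observations add Gaussian noise (default sd 0.3 kg —
hydration and clothing variation), days are dropped with the
missingness probability, and foreign weights are injected with an
offset of at least 6 % so ground truth for the 5 % filter is
unambiguous. It emulates measurement noise, missingness and
contamination; it does **not** emulate circadian or menstrual-cycle
weight dynamics, water-weight transients in the first diet week, or
auto-correlated noise — so passing end-to-end tests demonstrate the
engine's logic, not clinical performance on real scales.

## Problem sizes and numerical choices

Monte-Carlo summaries in the tests and the acceptance script use 200
synthetic clients for the recovery/green/trigger rates (90-day
horizons; 25–50 clients for auxiliary tallies), 1000 randomized series
for the flag-classifier cross-check, and exhaustive enumeration
(all $2^5$ patterns) for the trigger truth table — sizes at which the
binomial error of the checked rates is well under the asserted
margins. Intake search bounds are maintenance ±2500 kcal/day with a
0.05 kcal optimizer tolerance; the composition inverse uses
`uniroot` at $10^{-10}$ tolerance; ODE tolerances are $10^{-9}$
relative. Ties: a weight exactly on a zone bound is *in* the zone; a
deviation of exactly 5 % is *retained*; a step count exactly at goal
is *met*.

## Known limitations

* One calibrated compensation coefficient cannot separate adaptive
  thermogenesis from activity drift; intake estimates inherit any
  mis-specification of expenditure as a bias, which is why recovery
  tests are run against the generator's matched truth.
* The model is for adults at light-to-moderate activity; high-exercise
  programs (which need a modified partition curve) are out of scope.
* A perfectly flat-weight (zero-adherence) client under the default
  ±2 % band first exits the zone around day 35, because the
  12-month-calibrated prediction has only fallen ~1.6 kg by day 30.
  Out-of-zone triggering within the first month is therefore not
  achievable under the default band for a maintenance-intake client —
  the first toolbox recommendation lands around day 37–40. Programs
  wanting earlier escalation must narrow the band (at the cost of
  false reds from scale noise) or trigger on estimated intake instead.
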