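---
title: "Quantifying crypt-villus cell kinetics from pulse-chase labeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying crypt-villus cell kinetics from pulse-chase labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cveukinetics)
```

## The biological system and the measurement

The small-intestinal epithelium renews continuously: cells born in the
crypts migrate up the neighbouring villus and are shed from its tip within
days. `cveukinetics` analyses this turnover on the **crypt-villus
epithelial unit (CVEU)** — a one-dimensional column of cells running from
the base of a crypt to the tip of the adjacent villus, as scored on
transverse tissue sections.

The measurement is a thymine-analog pulse-chase: a single injection of
BrdU or IdU labels cells in S phase; the label is inherited by daughters
and diluted below detection after roughly 4–5 divisions. Each scored CVEU
yields a binary vector (position 1 at the crypt base; 1 = labeled), at
least 30 CVEUs per animal and time point. Averaging the scores per
position gives a labeling profile; summing the profile below and above the
crypt-villus boundary gives labeled-cell counts for the two compartments.

## The two-compartment model

The crypt compartment (positions `1..N_C`) contains all proliferative
cells plus some non-proliferative ones and keeps a constant size, so cell
production is balanced by transfer onto the villus. Writing `L_C`, `L_V`
for labeled cells in crypt and villus:

* while `L_C < L_C*`: `dL_C/dt = delta * L_C`, `dL_V/dt = 0` — labeled
  cells proliferate at the specific rate `delta` (per hour, net of death)
  and none have reached the boundary region yet;
* once `L_C` reaches the transfer threshold `L_C*` (at time `t1`): the
  crypt is saturated with label, `L_C` stays at `L_C*` and the villus
  gains `delta * L_C*` cells/h;
* once `L_V` reaches a second threshold `L_V*` (at `t2`): labeled cells
  also leave the villus tip at the specific shedding rate `gamma`, and
  `L_V` relaxes at rate `gamma` toward the balance level
  `delta * L_C* / gamma`.

The gates are Heaviside functions evaluated with `H(0) = 1`, so each
process is active exactly at its threshold and the phases are the
half-open intervals `[t1, t2)`, `[t2, Inf)`. The thresholds and the phase
times are interchangeable parameterizations
(`thresholds_from_times()`): `L_C* = L_C0 e^{delta (t1 - t0)}`,
`L_V* = L_V0 + delta L_C* (t2 - t1)`.

Two caveats the implementation makes explicit:

* the closed-form shedding phase (`explicit_solution()`) solves the gated
  system only when `delta * L_C* >= gamma * L_V*`; otherwise the gated
  dynamics would hold `L_V` at the threshold and the function warns that
  it extrapolates;
* labeled counts are real-valued throughout — they are sums of labeled
  proportions over many CVEUs, not integers.

Because experimental data are collected before shedding of labeled cells
begins, all fitting uses the pre-shedding form (`pre_shedding_solution()`),
and `gamma`/`t2` are optional parameters used only in forward simulation.

## Boundary estimation

The crypt-villus boundary (equal to the crypt size `N_C` in a
one-cell-wide column) is estimated from the profile observed at the
experiment's time zero — two hours after injection, when the analog is no
longer available for uptake: the boundary is the lowest position *above
the profile peak* at which the labeled proportion falls below 0.01
(`estimate_boundary()`). The scan starts above the peak because the
two-hour profile is also low near the crypt base; a global scan would
return a base position. With 30 CVEUs the estimate resolves proportions
down to 1/30, so the boundary carries a sampling error of roughly ±2
cells, matching the between-animal dispersion reported for this
measurement.

## Fitting

`fit_cveu()` fits the pre-shedding solution jointly to the crypt and
villus count series by nonlinear least squares on the `log(L + 1)` scale
(variance homogenization; both compartments weighted equally — the
neutral choice given only the transform is prescribed). The optimizer is
bounded Levenberg-Marquardt (`minpack.lm::nls.lm`) restarted from five
deterministic starting points spanning `delta` in `[0.01, 0.2]` and `t1`
in `[2, 30]` h, which removes any dependence on a single starting guess
without introducing randomness. Standard errors are the Gauss-Newton
asymptotic errors `sigma^2 (J'J)^{-1}` at the optimum — the standard
nonlinear-regression output.

Fixed and free parameters depend on the regime:

| scheme       | fixed                  | free                    |
|--------------|------------------------|-------------------------|
| `control`, `omomyc` | `t0 = 0`, `L_V0 = 0`  | `delta`, `t1`, `L_C0` |
| `arac_early` | `t0 = t1 = 15` h       | `delta`, `L_C0`, `L_V0` |
| `arac_late`  | `t0 = t1 = 25` h       | `delta`, `L_C0`, `L_V0` |

In the proliferation-arrest (Ara-C) schemes the labeled front is already
on the villus at `t0`, so transfer is taken to start at `t0` (`t1 = t0`)
and `delta` is allowed below zero — "no proliferation" must be an interior
hypothesis for the `|delta| < 2 se` test to be meaningful.

### Exclusion of dilution- and shedding-affected points

The model describes neither label dilution (which makes crypt counts fall
once lineages pass the detection limit) nor shedding (which caps villus
counts), so affected points are excluded before fitting
(`exclude_diluted()`), per compartment:

* **crypt**: all points from the first time the count drops below
  `f = 0.9` times its running maximum and never recovers;
* **villus, dilution**: the villus integrates transfer that happened
  *earlier*, so dilution reaches it about one sampling interval after the
  crypt's decline onset; villus points are dropped from there on. (On
  simulated data this reproduces, at large CVEU numbers, the exclusion
  set defined by a detectable-vs-total divergence above 5%.)
* **villus, shedding**: points after the first interval from which every
  subsequent slope stays below `(1 - f)` times the series' maximum slope.

`f` is exposed because the rule is qualitative in origin. When fewer than
three time points survive — typical when the label is already several
generations old at the window start, as in the post-arrest regime — the
factor is relaxed stepwise (0.9, 0.8, 0.6, 0.4, 0.2) until a fittable
dataset remains: the rule exists to remove contaminated points, not to
veto the fit. A manual index list overrides the automatic rules.

## Kinematics and transit times

With constant `delta` across crypt positions, mitotic pressure moves a
cell at position `x` at `V_x = delta * x` cells/h, so the velocity at the
boundary — equal to the crypt's cell production rate — is `V_CV = delta *
N_C`. Transit from crypt base to boundary is
`integral from 1 to N_C of dx / (delta x) = ln(N_C) / delta` (the lower
limit is position 1: positions are 1-based and `V_x` vanishes at `x = 0`);
villus transit is the remaining cell count divided by `V_CV`
(`derive_kinematics()`). The labeled-front velocity on the villus,
`V_LF`, is the ordinary least-squares slope of front position (µm) on
time (`fit_front_velocity()`); the ratio `V_CV / V_LF` estimates the cell
density of the epithelium and should be constant across tissues if
proliferation alone drives migration.

```{r transit}
k <- derive_kinematics(list(delta = 0.0760, n_crypt = 20),
                       cveu_length_cells = 99.7,
                       density_cells_per_10um = 1.25)
k
```

## Statistical comparison of production rates

Groups are compared through the posterior of `V_CV = delta * N_C`
(`compare_production_rates()`): `delta` is given an inverse-gamma
posterior and `N_C` a log-normal posterior, each moment-matched so the
distribution's mean and standard deviation equal the fitted estimate and
its standard error (`moment_match()`; the closed forms round-trip
exactly). The two are drawn independently — the product has no joint
term — 10,000 draws by default, and a difference is declared significant
when `P[V_CV(i) > V_CV(j)] > 0.95`. `V_LF` gets a normal posterior;
draws at or below zero are rejected and redrawn with a reported count
(negligible at realistic means). Velocity-ratio contrasts
(`velocity_ratio_difference()`) use the central 95% interval of the
difference of per-draw ratios. All Monte Carlo functions accept an
explicit seed.

## The synthetic-data generator

`simulate_cveu()` is an agent-based model of one CVEU: cells at crypt
positions `1..N_C` divide as independent Poisson processes at rate
`delta`; a division inserts the daughter above the mother and shifts all
higher cells up one position (mitotic pressure), shedding the cell that
leaves the tip; label and a generation counter are inherited, and label
older than `detection_limit_generations = 5` divisions scores 0. Event
times are exact (exponential waiting times on the active clock), arrest
windows suspend divisions, and each sample time receives its own
independent CVEUs — a cross-sectional design, as each experimental time
point comes from a different animal. CVEU lengths are drawn per unit from
a normal with the tissue's reported mean and dispersion, truncated at
`N_C + 1`.

The initial labeling profile mimics the observed two-hour profiles: zero
at and above the boundary (so the 0.01 criterion lands at `N_C`), rising
from a partially labeled base to a plateau over intermediate crypt
positions, then falling to a low foot just below the boundary; it is
scaled so the expected labeled count per CVEU equals the tissue's
reported two-hour total (8.2 for healthy duodenum, etc. —
`cveu_preset()`). No quantitative profile is published, so the shape is
calibrated only to those totals and to the qualitative features of the
observed count series: near-exponential early crypt growth, villus
accumulation turning linear, and a late crypt decline from dilution.

Two emergent properties of this generator are worth knowing:

* **Dilution arrives at `2 * delta * t` generations, not `delta * t`.** A
  random descendant's generation count is size-biased (lineages that
  divided more contribute more cells), so detectable counts start
  diverging from true counts near `2 delta t ≈ detection limit` — about
  40 h in the healthy ileum, consistent with the observed onset of the
  crypt count decline.
* **Boundary cuts below the true crypt size do not distort the estimated
  production rate.** Every column position below the true boundary
  proliferates at the same rate, so the joint fit recovers the total
  detectable production at any cut; the instability seen on real tissue
  for too-low boundaries reflects spatial structure (a non-proliferative
  upper crypt region) this deliberately uniform generator does not have.
  The sensitivity sweep (`boundary_sensitivity()`) therefore shows the
  plateau at and above the true boundary — stable `delta * N_C`, with
  `delta` decreasing compensatorily — which is the diagnostic used to
  justify the boundary criterion.

```{r pipeline}
sim <- simulate_cveu(cveu_preset("control_ileum"), seed = 1)
res <- run_pipeline(sim$scores, density = sim$config$density)
res
```

## Numerical choices and problem sizes

* `H(0) = 1` everywhere; phases are half-open intervals.
* Bounded fits: `delta >= 1e-4` for homeostatic schemes (growth must be
  positive for `t1` to be identified), `delta >= -0.5` for arrest
  schemes; `t1` in `[t0, max(t)]`; `L_C0` in `(0, N_C]`.
* Tolerances: `ftol = ptol = 1e-12`, 500 iterations; the five-restart
  grid is deterministic.
* Closed forms are validated against numerical integration of the gated
  right-hand side, with the integrator restarted on the threshold
  manifold at the phase changes (the standard event-handling treatment of
  a discontinuous right-hand side); agreement is required to a relative
  1e-6 over random parameter sets.
* Reference problem sizes used throughout the tests: 30 CVEUs per time
  point, 8 sample times over 0–40 h for homeostatic regimes, 13 sample
  times over 15–74 h for the arrest design, and 20 seeded replicates for
  recovery summaries; these match the scale of the underlying scoring
  experiments while keeping a full run in seconds.

## What passing tests do and do not show

The simulator shares the fitted model's skeleton (single average
`delta`, fixed crypt size, 1-D mitotic pressure) but not its closed form:
transfer switches on gradually as the label bulk reaches the boundary,
label washes out of the crypt base, and dilution truncates the usable
window. Parameter recovery through the full pipeline therefore tests the
whole chain — scoring, profiles, boundary, exclusion, fitting — under
realistic violations of the piecewise model. It does **not** establish
that real crypts have position-independent division rates (they do not:
base cells cycle slower, which is precisely why real late-window label
persists longer than this generator predicts), nor that the exclusion
rule identifies dilution on data whose noise structure differs from
binomial scoring noise. Post-arrest (`arac_late`) recovery is the
hardest regime: the label there is several generations old, the usable
window is short, and single-replicate estimates carry ~20% sampling
error; conclusions in that regime should rest on replicate medians, as
the tests do.
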