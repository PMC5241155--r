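# cveukinetics

Quantifies cell proliferation and migration in the small-intestinal
epithelium from thymine-analog (BrdU/IdU) pulse-chase data scored along
crypt–villus epithelial units (CVEUs). The package is for
quantitative biologists and biostatisticians who track labeled cells on
1-D crypt-to-villus-tip columns and want kinetic parameters — a specific
proliferation rate, migration velocities, transit times — plus principled
group comparisons, rather than descriptive label-front plots.

## The model

A CVEU is a column of cells, positions `1..L` from the crypt base; the
crypt compartment is `1..N_C` and keeps constant size, so proliferation
is balanced by transfer onto the villus. Labeled cells obey the
threshold-gated system

    dL_C/dt = δ·L_C·[1 − H(L_C − L_C*)]
    dL_V/dt = δ·L_C·H(L_C − L_C*) − γ·L_V·H(L_V − L_V*),   H(0) = 1

with explicit piecewise solutions: exponential crypt growth at the
specific rate δ (h⁻¹) until the transfer threshold `L_C*` is reached at
time `t1`, then linear villus accumulation at `δ·L_C*`, then first-order
shedding at rate γ once the villus holds `L_V*` labeled cells. Fitting
uses the pre-shedding form on the variance-homogenizing `log(L+1)` scale.
Downstream, mitotic pressure gives the velocity `V_x = δ·x` at crypt
position `x`, the boundary velocity / crypt production rate
`V_CV = δ·N_C`, crypt transit `ln(N_C)/δ`, villus transit
`(L − N_C)/(δ·N_C)`, and the labeled-front velocity `V_LF` by linear
regression of front position on time. Production rates are compared
across groups by Monte Carlo draws from moment-matched posteriors
(inverse-gamma for δ, log-normal for `N_C`, normal for `V_LF`),
significant when `P[V_CV(i) > V_CV(j)] > 0.95`.

An agent-based CVEU simulator (Gillespie dynamics, mitotic pressure,
inherited label with generation-count dilution, arrest windows,
per-regime presets) generates full synthetic datasets so the entire
pipeline can be validated end to end.

## Worked example

Simulate a healthy-duodenum pulse-chase experiment (30 CVEUs at each of
8 sample times, δ = 0.0760 h⁻¹, crypt size 20) and run the full analysis:

```r
library(cveukinetics)
sim <- simulate_cveu(cveu_preset("control_duodenum"), seed = 7)
res <- run_pipeline(sim$scores, density = sim$config$density)
res
#> CVEU labeling analysis
#>   boundary N_C = 20 cells; 8 sample times
#> Two-compartment CVEU label model fit (scheme: control )
#> Free parameters:
#>             delta     t1   l_c0
#> estimate 0.074760 3.7230 7.3990
#> se       0.006495 0.4043 0.5482
#> Fixed: t0 = 0, l_v0 = 0
#> Boundary N_C = 20; RMSE (log(L+1) scale) = 0.0827; 9 points used, 7 excluded
#> Labeled-front velocity: V_LF = 12.11 um/h (se 0.267), K = 111.1 um, n = 8
#> CVEU kinematics (mitotic pressure)
#>   V_CV = delta * N_C = 1.495 cells/h = 11.96 um/h
#>   transit: crypt 40.07 h + villus 53.86 h = 93.93 h total
```

Reading the output: the crypt–villus boundary was recovered at position
20 from the two-hour profile; the fitted proliferation rate 0.0748 h⁻¹
is within 2% of the generating 0.0760 h⁻¹ (dilution-affected late points
were excluded automatically); the crypt produces ≈1.5 cells/h, the
labeled front moves at ≈12 µm/h — equal to the boundary velocity
expressed in µm, as it must be when proliferation drives migration — and
a newborn cell needs ≈94 h to travel from crypt base to villus tip.

Group comparison at fitted values (healthy vs Myc-inhibited duodenum):

```r
ctrl <- posterior_spec(0.0760, 0.0147, 20, 2.0, label = "control duodenum")
omo  <- posterior_spec(0.0547, 0.00665, 18, 0.8, label = "omomyc duodenum")
compare_production_rates(ctrl, omo, seed = 1)
#> P[V_CV(i) > V_CV(j) | data] = 0.958 (significant at 0.95)
#>              group  mean    sd
#> 1 control duodenum 1.520 0.334
#> 2  omomyc duodenum 0.982 0.128
#> 95% interval of difference: [-0.0525, 1.33] cells/h
```

See `vignette source in vignettes/cveu-kinetics.Rmd` for the full
methods account: model assumptions, fitting schemes per experimental
regime, the exclusion policy for dilution- and shedding-affected points,
and what the simulator does and does not emulate.

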