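# polvdyn

Kinetic and single-molecule analysis of conformational regulation of the
*Escherichia coli* DNA polymerase V mutasome (pol V Mut = UmuD′₂C‑RecA‑ATP).

Pol V Mut is a conformational switch: it assembles inactive, is activated by
ATP/ATPγS binding (which reorients the RecA subunit relative to UmuC), copies
primer/template DNA while active, and then switches off — *dynamically* during
synthesis or *statically* during idle incubation — until a RecA* filament
donates a fresh RecA molecule. `polvdyn` implements the quantitative analyses
that characterize this switch, plus seeded synthetic generators for every
input so the whole pipeline can be validated end to end.

## What it computes

**Dynamic deactivation.** Primer extension under Poisson depletion of active
enzyme follows

    P(t) = 1 − exp{ −(k/D) (1 − e^(−D t)) }

with intrinsic synthesis rate constant *k* (min⁻¹) and deactivation rate *D*
(min⁻¹); `−ln(1 − P) ≈ k t` at short times, and the plateau `1 − e^(−k/D)`
sets how many rounds of synthesis complete before switch-off
(`pe_model()`, `fit_initial_rate()`, `fit_deactivation()`, `plateau()`,
`predict_rounds()`, `percent_extended()`).

**Static deactivation.** Initial rate from the activity loss at 30 min,
`−ln A(30)/30`, and the two-point Arrhenius energy
`Ea = R ln(r_hi/r_lo)/(1/T_lo − 1/T_hi)`
(`static_rate()`, `arrhenius_ea()`).

**smFRET binding.** Per-frame efficiency `E = I_A/(I_D + I_A)`, threshold-run
idealization of trajectories into binding events with censoring flags, bound
dwell and rebinding-time extraction, exponential dwell fits by maximum
likelihood (`τ̂` = mean, SE `τ̂/√n`) or histogram fitting, and the affinity
calculus `k_dissoc = 1/τ_bound`, `k_assoc = 1/(τ_rebind·[E])`,
`K_D = k_dissoc/k_assoc`, plus Förster conversion `r = R₀((1−E)/E)^(1/6)`
(`fret_efficiency()`, `detect_events()`, `dwell_times()`, `rebind_times()`,
`efficiency_histogram()`, `fit_dwell()`, `affinity()`, `kd_ratio()`,
`survival_fraction()`, `forster_distance()`).

**Three-state switch.** An exact-event-time stochastic simulator of the
inactive → activated → deactivated switch with RecA* reactivation dosing,
whose ensemble extension must reproduce the closed-form kinetics
(`sim_state_ensemble()`, `reactivation_response()`).

## Worked example

```r
library(polvdyn)

## dynamic deactivation: simulate a 37 C ATPgS time course and refit it
tc <- sim_extension(k = 0.008, D = 0.028,
                    times = c(0, 15, 30, 60, 90, 120, 180, 240, 300),
                    noise_sd = 0.01, n_replicates = 3, seed = 101)
pe_mean <- aggregate(pe_fraction ~ time_min, tc, mean)
fit <- fit_deactivation(pe_mean$time_min, pe_mean$pe_fraction)
fit
#> Dynamic-deactivation fit (depletion form)
#>   k = 0.00784 min^-1 (SE 0.00034)
#>   D = 0.02742 min^-1 (SE 0.0014)
#>   plateau P(Inf) = 0.2487; residual RMS = 0.00495; n = 9 points
predict_rounds(fit$k, fit$D, dna_excess = 5)
#> [1] 1.24
```

The fitted rates recover the generating values (k = 0.008, D = 0.028 min⁻¹)
within their standard errors, and the plateau of ~0.25 at 5-fold DNA excess
means the enzyme completes just over one round of synthesis before dynamic
deactivation halts it.

```r
## smFRET: trajectories -> events -> dwell MLE -> affinity
sim <- sim_fret(n_traj = 300, tau_bound = 6.1, tau_unbound = 17, E_bound = 0.7,
                frame_dt = 0.3, duration = 180, I_total = 500, noise_sd = 50,
                seed = 202)
es <- detect_events(sim$trajectories, threshold = 0.2, min_frames = 2)
fit_dwell(dwell_times(es))
#> Exponential dwell fit (mle): tau = 6.34 +/- 0.14 s (N = 2121)
fit_dwell(rebind_times(es))
#> Exponential dwell fit (mle): tau = 16.3 +/- 0.37 s (N = 1908)
efficiency_histogram(es, bin_width = 0.05)
#> FRET efficiency histogram: 46533 bound frames, mode bin at 0.7

## affinity from the published dwell statistics of the two nucleotide conditions
kd_ratio(affinity(6.1, 17, 2), affinity(3.0, 13, 5))
#> [1] 3.887255
forster_distance(0.2, R0 = 51)
#> [1] 64.25597
```

The detected dwell scale (6.3 s) and rebinding scale (16.3 s) recover the
generating values (6.1 s and 17 s); the modal efficiency bin sits at the
generating bound-state efficiency 0.7. Composing the published dwell
statistics gives a ~3.9-fold stronger affinity with ATPγS than with ATP, and
an efficiency of 0.2 corresponds to a 64 Å donor–acceptor separation for the
AF555/AF647 pair.

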