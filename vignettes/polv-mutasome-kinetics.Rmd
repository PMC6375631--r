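---
title: "Quantifying conformational regulation of pol V Mut: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying conformational regulation of pol V Mut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polvdyn)
```

## The system

The *E. coli* translesion DNA polymerase V mutasome (pol V Mut =
UmuD′₂C‑RecA‑ATP) is regulated conformationally: the orientation of its RecA
subunit toggles the enzyme between a catalytically inactive assembly state, an
ATP‑activated state that binds primer/template (p/t) DNA and synthesizes, and
a deactivated state that can only be rescued by a fresh RecA monomer delivered
from a RecA* nucleoprotein filament. Deactivation happens on the hour scale,
both *dynamically* (during synthesis) and *statically* (during idle
incubation), faster at 37 °C than at 30 °C.

`polvdyn` packages the quantitative layer of this biology: the kinetic model
for extension time courses under dynamic deactivation, static‑rate and
two‑temperature Arrhenius estimates, the smFRET trajectory → binding‑event →
dwell‑time → affinity calculus, and a stochastic three‑state switch simulator
that must agree with the closed‑form kinetics. Every input can be generated
synthetically with known ground truth, so the whole pipeline is testable
without any measurement data.

## The dynamic-deactivation model

Primer extension is pseudo‑first order, `dP/dt = k' (1 − P)`, with `k' = k[E]`
proportional to the concentration of *active* enzyme. Dynamic deactivation
depletes the active pool as a Poisson process at rate `D`, so `[E](t) ∝
e^{−Dt}` and

> P(t) = 1 − exp{ −(k/D) (1 − e^{−Dt}) }.

This form has the three properties the experiments rely on: the short‑time
linearization `−ln(1 − P) ≈ k t` (used by `fit_initial_rate()` to seed `k`),
the `D → 0` limit `1 − e^{−kt}`, and a plateau `P(∞) = 1 − e^{−k/D}` that
measures how much DNA the enzyme copies before it switches off. With
`k = 0.008 min⁻¹`, `D = 0.028 min⁻¹` the plateau is 0.2485 — one round of
synthesis at 5‑fold DNA excess (where one round is 20% of primers); with the
30 °C parameters `k = 0.012`, `D = 0.01` it predicts ≈ 3.5 rounds
(`predict_rounds()`).

A widely circulated variant of the integrated equation,
`ln(1 − P) = −kt + k(e^{−Dt} − Dt − 1)/D`, is internally inconsistent: its
short‑time expansion is `−3kt`, not `−kt`, so it cannot be fit with an
initial‑rate seed and it distorts the plateau. We therefore implement the
self‑consistent integral above as the default and keep the variant behind
`form = "as-printed"` purely for comparison. A test pins the `−3kt` behavior
so the discrepancy stays documented.

`fit_deactivation()` is a bounded Levenberg–Marquardt least‑squares fit
(`minpack.lm`), unweighted by default and inverse‑variance weighted when
replicate SDs are supplied. Noiseless curves round‑trip `(k, D)` to at least
four significant figures, and the optimizer is checked against a brute‑force
parameter‑lattice search. `D` sits on a boundary when the data carry no
deactivation signal; the fit then returns `D ≈ 0` with `k` exact rather than
failing.

## Static deactivation and Arrhenius analysis

Static deactivation is summarized by the activity loss at a 30‑min reference
point. `static_rate()` uses the exponential convention `−ln A(30)/30` by
default — it reproduces a rate of 0.015 min⁻¹ from ~36% activity loss at
30 min, consistent with losing most activity within the hour — with the linear
convention `(1 − A)/30` behind a flag. `arrhenius_ea()` is the two‑point
formula `Ea = R ln(r_hi/r_lo)/(1/T_lo − 1/T_hi)`, `R = 1.9872×10⁻³
kcal mol⁻¹ K⁻¹`, `T = °C + 273.15`. Applied to the rounded printed rates
(0.008/0.015 and 0.017/0.021 min⁻¹) it gives 16.8 and 5.6 kcal/mol; published
estimates derived from unrounded rates are larger, so the *formula*, not any
particular energy value, is what the package contracts and tests.

## smFRET: trajectories to affinity

Efficiency per frame is `E = I_A/(I_D + I_A)`, clipped to [0, 1]; frames with
nonpositive total signal are flagged invalid. The original binding‑event
detection was unspecified software, so `detect_events()` is a deterministic,
parameterized replacement: maximal runs of at least `min_frames = 2`
consecutive frames with `E ≥ 0.2` (the lower edge of the observed efficiency
range) become events; runs touching either end of the trajectory are censored
and excluded from dwell statistics by default. Optional hysteresis bridges
single‑frame dropouts; it is off by default so the detector stays idempotent
and threshold‑monotone. Acceptor background is estimated per trajectory as the
median acceptor intensity over provisionally unbound frames and subtracted
before efficiencies are finalized — absolute intensities and backgrounds are
instrument conventions, not biology, so this stays configurable
(`background = "none"`).

Dwell times are exponential; `fit_dwell()` estimates the scale `τ` by maximum
likelihood (`τ̂` = sample mean, SE `τ̂/√n`) or by least‑squares fitting of a
single exponential to the dwell histogram, the convention used for published
residence‑time histograms. The MLE is the primary estimator: it is unbiased
with the expected `τ/√n` spread (property‑tested over 500 replicates), while
the histogram fit is unbiased but ~2× noisier at N ≈ 100–300, which is why our
tests check its bands on across‑seed means rather than single draws. We report
the asymptotic SE; published ± bands at the same N are about twice as wide
(consistent with a 2·SE convention), and the acceptance checks use those wider
printed bands.

The affinity calculus composes printed dwell statistics: `k_dissoc = 1/τ_bound`,
`k_assoc = 1/(τ_rebind · [pol V Mut])` with the rebinding time standing in for
the unobservable unbound time, and `K_D = k_dissoc/k_assoc`. With
`τ_bound = 6.1 s`, `τ_rebind = 17 s` at 2 nM (ATPγS) versus `3.0 s`, `13 s` at
5 nM (ATP), the K_D ratio is 3.89 — ATPγS‑activated pol V Mut binds p/t DNA
about 3.9‑fold more strongly. `forster_distance()` inverts
`E = 1/(1 + (r/R₀)⁶)` with `R₀ = 51 Å` for the AF555/AF647 pair: `E = 0.2`
maps to 64 Å. Note the inversion is only defined on `0 < E < 1`, and an
observed efficiency range reaching 1.0 is incompatible with any finite lower
distance bound — the package rejects the endpoints rather than guessing a
convention.

## The three-state switch simulator

`sim_state_ensemble()` simulates each molecule as a continuous‑time Markov
chain over State 1 (assembled, cannot bind DNA), State 2 (activated,
synthesizing), State 3 (deactivated), with exact exponential event‑time
sampling — the reporting grid introduces no discretization error. Activation
is instantaneous by default (`k_act = Inf`): ATP binding is fast relative to
deactivation and was never separately quantified. Reactivation is modeled as
an instantaneous Bernoulli restoration (probability `reactivation_eff`) at
explicit RecA* dosing times, since only the fact of rescue upon dosing is
established, not a concentration‑dependent rate. Static and dynamic
deactivation are exposed as two rates into the same State 3; whether they are
the same microscopic transition is unknown, and the parameterization stays
agnostic.

Ensemble extension accrues only from State‑2 occupancy:
`pe(t) = 1 − exp(−k_syn · Ā(t))` with `Ā(t)` the mean per‑molecule time spent
in State 2. Because the closed form equals `1 − exp(−k ∫ E[1(State 2)] dt)`,
the simulator must converge to `pe_model()` at `O(n^{−1/2})`; tests check
agreement within 3 binomial standard errors at every grid point for `n = 10⁴`
and that a full‑efficiency dose at 240 min re‑runs the plateau on the residual
unextended fraction, `1 − (1 − P∞)²`.

## What the generators emulate — and what they do not

* `sim_extension()`: the closed‑form curve plus additive Gaussian noise on the
  fraction scale, clipped to [0, 1]. Replicate means ± SD is how gel
  densitometry data are reported; the underlying densitometry noise model was
  never stated, so additive Gaussian is the simplest compatible choice.
* `sim_activity()`: exponential activity decay, noise as above, clipped to
  [0, 1.05] to allow slight over‑unity replicate noise.
* `sim_fret()`: alternating‑renewal two‑state trajectories starting unbound
  (the enzyme is added after acquisition starts), exponential dwells, fixed
  bound‑state efficiency 0.7, per‑channel additive Gaussian noise, optional
  exponential photobleach truncation. Frames take the state at their midpoint.
  The unbound donor level defaults to the total bound intensity and the
  unbound acceptor to zero; absolute levels were never published. Ground truth
  includes dwells shorter than one frame so detection bias is measurable.

Not emulated: camera/EMCCD noise physics, spectral crosstalk and gamma
correction, pixel‑level image formation, donor/acceptor blinking, and
multi‑state FRET. Passing tests therefore demonstrate the correctness of the
estimators on data satisfying the stated model assumptions, not robustness to
every instrumental artifact in real recordings.

## Numerical and statistical choices

* `(1 − e^{−Dt})/D` is evaluated via `expm1` with a series branch for
  `Dt < 10⁻⁸`, so `pe_model()` is continuous through `D = 0`.
* Default initial‑rate window: the first three points with `pe < 0.1`.
  The windowed least‑squares slope is biased low once deactivation bends the
  early points (about −14% for `k = 0.004, D = 0.015` sampled at 0/10/20 min —
  derived from the closed form and pinned in a test); this only seeds the
  nonlinear fit, which removes the bias.
* Event dwell = number of qualifying frames × frame interval, closed on both
  ends; single‑frame sub‑threshold gaps are not bridged unless hysteresis is
  enabled.
* Censored events are excluded from dwell samples by default (an inclusion
  flag exists for sensitivity analysis); no survival‑likelihood correction is
  attempted beyond exclusion.
* Completed dwells collected from a finite observation window are selected
  against long draws; at τ = 6.1 s in a 180‑s window the bias on the mean is
  about −0.2 s. Distribution‑level tests of the generator therefore use a
  3000‑s window where the effect is negligible, while pipeline‑level recovery
  is still checked at the study's 180‑s window with a 15% tolerance.
* Seeds: every stochastic function takes an explicit seed and restores the
  caller's RNG state; `derive_seeds()` fans a master seed into per‑stage child
  seeds so stages can be re‑run in isolation.

## Problem sizes used in the checks

The reproduction harness (`run_reproduction()`, `scripts/acceptance.R`) uses
the study's own scales: dwell samples of N = 298/258/218 over 20 replicate
seeds, 300 trajectories of 180 s at 0.3 s/frame with 10% intensity noise, and
10⁴ molecules in the ensemble check on a 0–300 min grid — sizes at which every
stochastic band tested is several estimator SDs wide.

## Known limitations

* The detector is a threshold‑run idealizer, not an HMM; it will fragment
  events whose within‑event efficiency dips below threshold for ≥ 2 frames at
  high noise.
* `τ_rebind` understates `τ_unbound` whenever the first binding event of a
  trajectory is missed, so `K_D` values inherit that convention; ratios
  between conditions are more trustworthy than absolute affinities.
* The MLE ignores censoring beyond exclusion; at 180‑s trajectories and
  τ ≈ 6 s this costs ≲ 10% and stays inside the tested tolerances, but
  longer‑lived complexes would need a survival likelihood.
* Arrhenius estimates from two rounded rates are extremely sensitive to the
  rounding; treat them as order‑of‑magnitude summaries.
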