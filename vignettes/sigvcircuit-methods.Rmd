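---
title: "Methods: the sigma-V / RsiV stress-response circuit in sigvcircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the sigma-V / RsiV stress-response circuit in sigvcircuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigvcircuit)
```

## The model

sigvcircuit simulates the lysozyme stress-response module of *Bacillus
subtilis*: the extracytoplasmic-function sigma factor σ^V, its membrane
anti-sigma factor RsiV, and their complex. The two genes sit in one operon, so
σ^V drives the production of both its activator (itself) and its inhibitor
(RsiV) — a *mixed* positive/negative autoregulatory loop. Lysozyme stress
activates the loop by triggering proteolytic cleavage of RsiV inside the
complex, which releases σ^V.

The state is the integer copy-number triple (free σ^V, free RsiV, complex),
denoted $(\sigma, R, C)$. The lysozyme input $L(t)$ is an arbitrary
piecewise-constant protocol. Seven reaction channels define the wild type:

| channel       | reaction                        | propensity                                  |
|---------------|---------------------------------|---------------------------------------------|
| production    | ∅ → σ^V + RsiV                  | $v_0 + v\,\sigma^n/(\sigma^n + K^n)$        |
| dilution (×3) | σ^V → ∅, RsiV → ∅, C → ∅        | $k_{deg}\,\sigma$, $k_{deg}R$, $k_{deg}C$   |
| binding       | σ^V + RsiV → C                  | $k_B\,\sigma R$                             |
| dissociation  | C → σ^V + RsiV                  | $k_D\,C$                                    |
| cleavage      | C → σ^V                         | $L(t)\,k_C\,C$                              |

Joint production of σ^V and RsiV in a single firing encodes the operon;
cleavage destroys RsiV while conserving σ^V (it moves from the complex to the
free pool); binding/dissociation conserve both totals. These per-event
conservation laws are asserted in the test suite on recorded event logs.

Default parameters (minutes and molecules): $v_0 = 0.1$, $v = 2.5$, $K = 60$,
$n = 2$, $k_{deg} = 0.01$, $k_B = 10$, $k_D = 5$, $k_C = 0.05$. They are the
package defaults of `circuit_params()` and every experiment.

### Variants

`circuit_variant()` perturbs the topology without touching the rate constants:
`second_copy_sigv` / `second_copy_rsiv` / `second_copy_operon` add a second,
identically regulated production channel for the given product(s);
`feedback_broken` replaces the autoregulated operon production with a constant
(inducible) rate equal to `magnitude`; `leak_sigv` / `leak_rsiv` add a constant
production channel of rate `magnitude` for one species; `hill_override`
replaces the Hill coefficient. `scale_system_size()` applies the
system-size map $v_0 \to \Omega v_0$, $v \to \Omega v$, $K \to \Omega K$,
$k_B \to k_B/\Omega$, which leaves the intensive mean-field dynamics invariant
while suppressing fluctuations as $\Omega$ grows.

## Numerical methods

**Gillespie SSA** (`simulate_ssa`): direct method, implemented in C++
(`src/engine.cpp`). Protocol boundaries are handled by clock re-draw — at each
segment boundary the exponential clock is redrawn rather than thinned, which is
exact for piecewise-constant rates. When the total propensity is zero the
simulation fast-forwards to the next segment boundary. Sampled output is
last-event-carried-forward onto a uniform grid (default 10 min, the imaging
cadence the synthetic data emulates).

**Chemical Langevin** (`simulate_cle`): Euler–Maruyama over reaction channels,
$\Delta x = \sum_j \nu_j (a_j h + \sqrt{a_j h}\, \xi_j)$. Negativity is handled
by *full truncation*: propensities are evaluated on the state clamped at zero
(the state itself may transiently dip below zero). The default step is
$h = 0.1/\max_j a_j$ with the maximum taken over the steady states of every
protocol level, so the fastest channel fires on average at most 0.1 times per
step.

**Mean-field companion** (`mean_field_path`, `steady_state`): the ODE
$\dot x = \sum_j a_j(x)\,\nu_j$ integrated segment-wise with `deSolve::lsoda`;
steady states from long-time integration on a logarithmic time grid followed by
a damped Newton polish. The mean-field model serves as a verification oracle:
at $\Omega = 50$ the SSA ensemble mean tracks the ODE path within 5 % relative
error (observed ≈ 1 %), decreasing in $\Omega$.

**Stationary comparisons**: `stationary_samples()` thins one long run. The
relaxation time of the circuit is $1/k_{deg} = 100$ min, so the default used in
validation is a thinning interval of 300 min (≈ 3 relaxation times); shorter
thinning leaves samples autocorrelated and inflates empirical
Kolmogorov–Smirnov distances for reasons unrelated to either integrator. With
decorrelated samples the CLE and SSA stationary laws of free σ^V agree to
KS $D \approx 0.05$ at the default parameters.

**Reproducibility**: every stochastic entry point takes a seed;
ensembles derive independent per-cell seeds from one base seed, so any
single cell can be re-simulated in isolation.

## In-silico experiments

All experiments burn in 500 min from $(0,0,0)$ at $L = 0$ before stress, and
score activation with one of two explicitly named rules:

* **half-maximum rule** (time courses): a cell's activation time is the first
  post-stress time its readout reaches half of its own final level (mean over
  a trailing window). Cells that never cross are censored and stay in
  denominators. A cell whose final level does not exceed its pre-stress mean
  is censored as a non-responder; this guards against flat traces trivially
  sitting above half of their own level, and can be disabled
  (`require_rise = FALSE`) when the scored episode is known to start from an
  activated state.
* **mean + 6 s.d. snapshot rule** (snapshot fractions): a cell is activated
  when its level exceeds the wild-type pre-stress mean plus six standard
  deviations. Bootstrap error bars use 1,000 resamples.

Chosen problem sizes and windows (package choices, also used by
`scripts/acceptance.R` and the acceptance tests):

* `dose_response`: $L \in \{0.5, 0.75, 1, 2, 4\}$, $N = 100$ cells per level,
  2500 min of stress. The window length matters: at 1500 min the slow
  activation tail at the two lowest doses is truncated and the mean activation
  times of adjacent doses become nearly indistinguishable; 2500 min lets every
  cell reach plateau. Both mean activation time (strictly decreasing in $L$)
  and mean plateau σ^V (strictly increasing) are reported.
* `copy_number_experiment`: $N = 999$, assay 30 min after stress, snapshot
  rule. Activated fractions order as
  2×σ^V ≥ 2×operon ≥ wild type ≥ 2×RsiV, and a second σ^V copy activates a
  nonzero fraction before any stress.
* `memory_experiment`: gaps {50, 200, 400, 800} min, $N = 99$ per arm plus a
  naive control arm. Three scoring choices are deliberate. (i) The first
  stress episode lasts 2500 min so that *every* cell activates before stress
  removal — the premise of a memory experiment is that stress is removed from
  an activated system; at 1000 min a tail of cells (mean first activation at
  $L = 1$ is ≈ 680 min) has never activated, and their slow "reactivation"
  would be misread as memory loss. (ii) The pre-stress reference for a
  restressed cell is its relaxed state during the recovery gap
  (`prestress_window = min(gap, 100)` min), not the earlier stress episode.
  (iii) Restress arms set `require_rise = FALSE`: every cell activated during
  the first episode, so the flat-trace degeneracy the non-responder censor
  guards against cannot occur, while the censor would misfire on cells that
  simply stay above half-maximum through a short gap — such cells are
  activated at the first frame, not non-responders.
* `feedback_comparison`: constitutive rates {0.1, 0.25, 0.5, 1, 2.5}
  (bracketing the wild-type pre/post production), $N = 100$; fold change is
  plateau over baseline per cell, undefined (never pseudo-counted) at zero
  baseline.
* `leak_scan`: added rates {0, 0.02, 0.05, 0.1} molecules/min — "small"
  increases up to doubling the operon leak $v_0 = 0.1$. Larger deltas saturate
  the activated fraction at 1 and carry no directional information.
* `hill_requirement_check`: arms derive their seeds from the Hill coefficient
  value, so arms with equal $n$ give identical distributions by construction.
* `parameter_robustness_scan`: every parameter halved and doubled around the
  default set; heterogeneity (s.d. of activation times, floor 15 min — about
  one frame) must survive each perturbation.

## Synthetic mother-machine data

`generate_mother_machine_ensemble()` emulates single-cell fluorescence traces:
a YFP reporter driven by the operon production rate with first-order
maturation (default 15 min) and dilution, integrated exactly per frame as a
two-stage linear cascade; multiplicative log-normal measurement noise
(mean 1); exponential length growth with division every 51 ± 13 min; a width
channel with an optional "sick" subpopulation of wide cells; frames every
10 min.

Two modes: `"ssa"` drives the reporter from simulated circuit trajectories;
`"programmed"` builds logistic step reporters whose switch times, baselines
and correlations are *known exactly*, so the estimators in `trace_analysis`
can be tested against ground truth. The emitted `switch_time` is the half-max
crossing of the *noiseless* reporter, so recovery tests measure robustness of
the estimator to measurement noise, not the (physically real)
maturation/dilution lag; the driving trajectory's own crossing is recorded
separately. `generate_priming_lineages()` grows channel-wise lineage forests
with division, death, and washout events for the two survival-counting rules
(`top3_longest` keeps the three longest-resident cells per channel;
`channel_end_exclusion` scores all cells except those near the open end,
estimated from pre-stress washout positions).

What the generator does *not* model: spatial imaging artifacts, segmentation
errors, photobleaching, correlated noise between channels, and asymmetric
division — it is an estimator test-bed, not a microscope simulator.

## Limitations

* The CLE is accurate only at copy numbers large enough for the Gaussian
  approximation; at the default (small) copy numbers it is validated against
  the SSA in distribution, not pathwise.
* Steady-state detection assumes the deterministic system settles within
  $10^5$ min; the multistability probe only checks a single high-σ^V initial
  condition.
* Activation scoring assumes uniformly sampled traces.
* All conclusions are about the model at the default parameter set; no fitting
  to experimental data is performed or supported.

## A worked example

```{r example, eval = FALSE}
net <- build_network()
traj <- simulate_ssa(net, step_protocol(500, 1, 2000), seed = 1)
acts <- activation_times(traj, sigv, stress_time = 500)
autoplot(traj)

dr <- dose_response(N = 100, seed = 1)
tidy(dr)
autoplot(dr)
```
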