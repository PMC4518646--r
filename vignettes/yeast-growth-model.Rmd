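---
title: "A process-based model of yeast growth in batch and fed-batch bioreactors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A process-based model of yeast growth in batch and fed-batch bioreactors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedbatchsim)
```

## The model

`fedbatchsim` simulates aerobic growth of *Saccharomyces cerevisiae* on
glucose in a stirred bioreactor, in batch or fed-batch operation. It is a
system-dynamics model: eight stocks connected by fluxes, with regulatory
feedback loops, rather than a genome-scale metabolic reconstruction. The
stocks are masses in grams — glucose `G`, a lumped glycolytic-intermediate
pool `P` (glucose-6-phosphate through pyruvate), ethanol `E`, structural
cell material `C_M`, reserves `R` (glycogen-like), a self-produced
inhibitor `I`, dead cells `D` — plus the medium volume `V` in litres.

Two assumptions organise everything:

1. **A central glycolytic hub.** All glucose enters `P`, and the
   *intracellular* concentration `[P] = P / ((B + R) c)` (with
   `B = P + C_M` the active mass and `c` the cell volume per dry weight)
   controls the cell's regulatory state. The sigmoid
   `ge = 1 / (1 + a exp(b [P]))` is the fraction of catabolism routed to
   respiration ("glucose effect" / repression of respiration at high sugar
   load); `mo = 1 - ge` is the overflow fraction routed to fermentation
   (Crabtree effect). High `[P]` also drives reserve accumulation and,
   above the threshold `tau`, cell death (`d` switches from 0 to 1 and the
   pools `P`, `C_M`, `R` decay into `D` at rate `delta`).
2. **Self-inhibition.** Growth-linked by-products are secreted into the
   medium in proportion (`rho`) to the anabolic fluxes and accumulate as
   `I`. Ethanol and inhibitor concentrations feed back on metabolism
   through the intensities `n_E = sigma_E [E]/[E]_max` and
   `n_I = sigma_I [I]/[I]_max`, multiplying the fluxes by `(1 - n)`
   factors. This is what makes a fed-batch culture stop growing long
   before any physical limit: the inhibitor load rises with cumulative
   growth itself.

The process rates are Michaelis–Menten in their substrate concentration
with first-order dependence on `B`: glucose uptake (further limited by
product saturation `1 - [P]/[P]_max`, the ethanol feedback, and optionally
a lag factor after inoculation), respiration of `P`, fermentation of `P`
to ethanol, respiration of ethanol, and reserve accumulation. The mass
balances assemble these with efficiency factors `eta_*` (g product per g
substrate); everything not fixed into biomass or by-products leaves as
CO~2~ and water, which are not tracked.

Because the feedback intensities can exceed 1 (the ethanol sensitivity is
`sigma_E = 1.4`), every limitation factor of the form `(1 - x)` is clamped
to `[0, 1]`. Without clamping, a saturated feedback would make a
one-directional flux run backwards, which has no physical reading.

## Feeding profiles and reactor volume

Fed-batch operation supplies glucose at concentration `c_F` with a
volumetric profile `F(t)`:

* `exponential`: `F(t) = F0 exp(mu (t - t_F))` with
  `F0 = M_F mu / (c_F y_R)` — the classic constant specific feed rate
  (SFR); under ideal conditions the population grows at `mu`.
* `two_phase`: exponential for `t_switch` hours, then constant at the rate
  reached at the switch (continuous), as in short fed-batch protocols.
* `logistic_mu`: the SFR itself decays logistically,
  `mu*(t) = m1 - m1 / (1 + exp(-m2 (t - t_F - m3)))`, so feeding eases off
  as the culture approaches its inhibitor-set capacity. The volumetric
  rate uses the closed-form integral of `mu*`.

The medium volume obeys `dV/dt = F(t)` starting from `V0` (the
`consistent` mode). The source tables for these experiments print instead
a closed-form volume `V(t) = M_F/(c_F y_R) exp(mu (t - t_F))`, which is
discontinuous at `t_F` (it implies a volume of ~0.015 l immediately after
feeding starts in a reactor stated to hold 1 l) and omits the `-1` of the
feed integral. We verified numerically that taking it literally makes
concentrations explode at feeding start, so the integrated volume is the
default and the printed law is kept only as `volume_mode = "tabulated"`
for comparison.

## Numerical treatment

The balances are stiff: glucose and `P` relax on time scales of minutes
while the culture evolves over days. Integration uses `deSolve::lsoda`
(the same family of variable-order stiff solvers as MATLAB's `ode15s`
used in the original study) with `atol = rtol = 1e-8`. Three
discontinuities are handled explicitly:

* the timeline is split at feeding start and, for two-phase profiles, at
  the exponential-to-constant switch, restarting the integrator at each
  break;
* the death switch `d` is a Heaviside step in `[P]`; by default the solver
  root-finds the crossing `[P] = tau`, stops there, and restarts, so the
  discontinuity never sits inside a solver step. (Death alone does not
  cause chattering: it removes `P`, `C_M` and `R` at the same rate, which
  leaves `[P]` invariant.) A smoothed steep-logistic switch is available
  (`death_switch = "smooth"`) for contexts without event support;
* tiny negative excursions of the state produced by the solver are treated
  as zero mass when fluxes are evaluated, which keeps all fluxes
  non-negative and the trajectory physical without altering the balances.

Output is reported on a fixed dense grid (default 0.05 h) independent of
internal steps, so quantities defined as grid sums (the feeding objective
below) are stable. Two independent checks guard the integration: a
deliberately naive fixed-step RK4 integrator at `h = 1e-3` h reproduces
the stiff solution of the batch scenario within 0.5% on all observables,
and tightening tolerances tenfold changes them by less than 0.1%.

The observable compared with optical density is
`[M] = (P + C_M + R + D)/V` — dead cells scatter light too, so they are
included; the non-viable fraction is `D/(P + C_M + R + D)`.

## Packaged scenarios

Seven scenario files ship with the package (`list_scenarios()`),
reproducing four strains: an aerobic batch culture of LBG H 1022 (diauxic
growth), a short two-phase fed-batch of CBS 8066, extended exponential
fed-batches of the prototroph CEN.PK113-7D (SFR 0.16 1/h) and the
auxotroph CEN.PK2-1C (SFR 0.1, 0.16, 0.2 1/h), and the variable
(logistic-mu*) feeding run. Kinetic parameters are the strain-calibrated
values; each file documents which setup entries are reconstructions of
typographically garbled or internally inconsistent table cells. Two
reconstructions deserve mention:

* the batch scenarios assume `V0 = 1` l (stated for the CEN.PK runs, not
  tabulated for the literature ones);
* for CBS 8066 the initial cell mass is set to the tabulated mass at
  feeding start (`M_F = 3.66` g) because the medium starts glucose-free,
  and the feed-design yield `y_R = 0.5` replaces the printed `0.1`: with
  `0.1` the initial feed is an order of magnitude above the uptake
  capacity of a 3.66 g culture and the run never consumes its ethanol,
  contradicting the reported behaviour of this experiment (ethanol
  depleted around 8 h, growth tracking the imposed SFR 0.3). With the
  reconstruction, the simulated ethanol is depleted at 7.8 h.

The CEN.PK2-1C triplets (SFR, end time, feed-start mass) are paired
positionally — (0.1, 31 h, 4.52 g), (0.16, 40 h, 4.14 g),
(0.2, 48 h, 4.14 g) — with the 0.16/40 h pairing fixed by the narrative
of the original experiments; the others are configurable.

## Calibration

`calibrate()` minimizes the unweighted least-squares objective

`SSE = sum (M_i - M_i*)^2 + sum (G_i - G_i*)^2 + sum (E_i - E_i*)^2`

over a user-chosen free parameter subset with the Nelder–Mead simplex
(`stats::optim`, the counterpart of MATLAB's `fminsearch` used
originally). Model values at observation times come from linear
interpolation of the reported grid. Design choices:

* the mass channel is compared to `[M]` (including dead cells), because
  the measured quantity is optical density and cannot exclude them;
* `R^2` is the coefficient of determination `1 - SS_res/SS_tot` (the
  original work reports R² without defining it; this is the standard
  reading);
* positivity and `(0, 1]` efficiency bounds are enforced by log/logit
  reparameterization, keeping the simplex unconstrained; jointly invalid
  candidates (e.g. `eta_FE + eta_FP > 1`) and failed integrations are
  penalized with a large finite objective;
* channels are unweighted by default, as in the original definition, even
  though the mass channel spans ~100 g/l while glucose stays near zero; a
  weight vector is available;
* convergence tolerances default to `reltol = 1e-6`, at most 2000
  iterations; which of the 27 parameters are free is a user decision (the
  original study does not state its free set).

## Feeding optimization

`optimize_feeding()` searches the logistic-profile parameters
`(m1, m2, m3)` minimizing `OF = 1/max(C_M(t)) + sum_i E_i` — maximize
peak biomass, and penalize any ethanol exposure, summed over the
reporting grid. Two caveats are structural. First, the grid sum makes the
absolute OF scale grid-dependent, so only the optimum's location is
comparable across implementations. Second, the ethanol term dwarfs the
biomass term whenever ethanol appears at all, so the optimum lies on a
nearly flat ridge of profiles that feed close to the respiratory capacity
early and throttle sharply as the inhibitor accumulates: quite different
`(m2, m3)` combinations achieve OF values within 0.05% of each other. The
recovered `m1` (the initial mu* plateau) is therefore the meaningful
quantity, and `m2`, `m3` are reported without being interpreted. The
search uses deterministically perturbed multi-starts under a seed (five
around `(0.16, 0.16, 10)` for the packaged analysis) followed by a deeper
simplex polish of the best result: without the polish the simplex stalls
at seed-dependent points along the ridge (`m1` anywhere in ~0.17–0.21),
while the polished ridge minimum is stable at `m1 ≈ 0.162` for the
auxotroph scenario.

## Synthetic observations and recovery

`generate_observations()` emulates the monitoring protocol of these
experiments: hourly sampling of mass, glucose and ethanol concentrations,
triplicate measurements with relative standard deviation up to 5%,
reported as replicate means. Noise is multiplicative Gaussian
(`truth * (1 + eps)`, `eps ~ N(0, cv)`), truncated at zero — chosen
because the protocol reports *percent* standard deviations. What the
generator does **not** emulate: optical-density calibration error,
sampling-volume withdrawal, autocorrelated drift in the analytical
assays, or model misspecification. Passing recovery tests therefore show
identifiability of the chosen parameters under the model's own dynamics
and honest measurement noise — not robustness to a wrong model.

`recovery_experiment()` chains simulate → corrupt → refit across seeds.
With the batch scenario, hourly sampling, `cv = 0.05` and `v_G`, `v_F`
free from a ±20% start, the median absolute relative error over 10 seeds
stays below 10%; with `cv = 0` recovery is exact to better than 1%.

## Problem sizes and runtimes

The test suite and the packaged analysis scale their problem sizes to
desk use: scenario simulations report on 0.05 h grids (a few hundred to a
thousand points, each solved in about a second); calibrations in tests
use 0.2 h grids, where interpolation error is orders of magnitude below
measurement noise; the recovery study uses 10 seeds; the feeding
optimization uses 150 simplex iterations per start. These choices are
stated here because they are part of the reported numbers: a coarser OF
grid rescales the ethanol term, and longer simplex runs wander further
along the flat OF ridge without materially changing `m1`.

## Known limitations

* No oxygen state: the experiments held dissolved oxygen at 30%
  saturation, and the model assumes fully aerobic conditions throughout.
* The inhibitor is phenomenological — one lumped pool with a linear
  concentration feedback; its chemical identity is outside the model.
* The printed closed-form volume law could not be reconciled with the
  stated initial volume; results use the integrated volume (see above).
* The auxotroph's end-of-run non-viable fraction computes to ~38% here
  against a reported ~50%; with every tabulated parameter fixed, the
  death switch trips at 34.5 h, which bounds the death exposure. The
  prototroph's ~28% (reported ~30%) and all other headline quantities
  reproduce within their stated bands.
* Fits to the original measured time series cannot be reproduced because
  those series exist only as figures; the packaged checks target the
  simulation-level quantities instead.
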