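---
title: "Model, numerics and design choices in statswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, numerics and design choices in statswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`statswitch` simulates a dimensionless kinetic model of the decision between
apoptosis and survival in a tumour cell, driven by the mutual antagonism of
two transcription factors: STAT1 (pro-apoptotic, induced by interferon-beta)
and STAT3 (anti-apoptotic, driven by the JAK2 kinase). Each factor
autocatalyses its own production through a Hill-type term that the other
factor inhibits:

$$
\frac{dS_1}{dt} = \lambda_{S1} S + \frac{k_1 k_2^2}{k_2^2 + \alpha S_3^2} - S_1,
\qquad
\frac{dS_3}{dt} = \frac{\lambda_k + \lambda_J J}{K + \lambda_{S2} S}
 + \frac{k_3 k_4^2}{k_4^2 + \beta S_1^2} - \mu_3 S_3 .
$$

Downstream, STAT1 suppresses and STAT3 drives the anti-apoptotic gate-keeper
Bcl-2 ($B$), which in turn suppresses the pro-apoptotic effector BAX ($X$):

$$
\frac{dB}{dt} = \lambda_1 + \frac{k_5 k_6^2}{k_6^2 + \gamma S_1^2}
 + \lambda_3 S_3 - \mu_B B,
\qquad
\frac{dX}{dt} = \lambda_2 + \frac{k_7 k_8^2}{k_8^2 + \delta B^2} - \mu_X X .
$$

A cell is *apoptotic* when Bcl-2 is strictly below its threshold
($B < B_{th} = 1.44$) **and** BAX strictly above its threshold
($X > X_{th} = 0.3$); the indicator $I$ of that condition gates both the
STAT1-mediated growth suppression and the kill term of the logistic tumour
equation,

$$
\frac{dT}{dt} = r\Bigl(1 - k_9\,\tfrac{S_1^2}{k_{10}^2 + S_1^2}\,I\Bigr)
 T\Bigl(1-\tfrac{T}{T_0}\Bigr) - \mu_T T I .
$$

Two drugs enter as first-order pharmacokinetic compartments: interferon-beta
$S$ (infusion $u_S$, decay $\mu_S = 4.8$) raises STAT1 and suppresses the
STAT3 source, and cisplatin $D$ (infusion $u_D$, decay $\mu_D = 10$)
degrades JAK2 at rate $\gamma_D D$, removing STAT3's driver. All
concentrations, times and volumes are dimensionless (the scaling constants
live in `reference_scales()`; `nondimensionalize()` / `dimensionalize()`
convert, with time mapped through the dimensional STAT1 turnover rate).

The switch behaviour comes from the bistability of the
STAT1–STAT3–Bcl-2–BAX subsystem: at `J = 0` the equilibrium branch folds
twice, producing a window of IFN-beta levels (about $[0.30, 0.53]$ at the
defaults) in which an anti-apoptotic (Pt) and an apoptotic (Pa) state
coexist, with hysteresis under slow ramps. At `J = 1` the branch is single
and uniformly anti-apoptotic for $S \in [0,1]$ — JAK2 makes the cell
IFN-resistant, which is why the cisplatin co-treatment matters.

## Parameters, defaults, and the two calibrated coefficients

All rate constants default to the published dimensionless values
(`stat_params()` prints them). Two coefficients — `lambda_S1` (IFN-beta →
STAT1 source) and `lambda_S2` (IFN-beta suppression of the STAT3 source) —
are not part of that published set. Both default to 1 and
`calibrate_source_coefficients()` refines `lambda_S1` by a golden-section
scalar search so the two fold points of the `J = 0` bifurcation scan match a
target window (default $[0.3, 0.53]$), minimizing the larger of the two
fold-point deviations. At the defaults this search is essentially a fixed
point: $\lambda_{S1}^\ast \approx 1.005$.

`lambda_S2` is held at 1 during calibration. That choice is *identified* by
the window: re-matching the upper fold via `lambda_S1` while increasing
`lambda_S2` drags the lower fold away from 0.3 monotonically
(`lambda_S2 = 4` gives $S_m \approx 0.256$, `= 10` gives $\approx 0.199$),
so the joint two-parameter calibration against both folds lands back at
$(\approx 1, \approx 1)$.

**Known limitation.** The dimensionless dosing scale is sensitive to
`lambda_S2`: it sets the IFN-beta level at which the `J = 1` branch crosses
into the apoptotic region (about $S \approx 1.6$ at the default, i.e. an
infusion rate of $\approx 1.6\,\mu_S \approx 8$). Every minimum-dose,
resting-time and optimal-control quantity scales with that entry level,
while the bifurcation window constrains it only weakly. Users comparing
absolute infusion rates against external data should treat `lambda_S2` as
the uncertain coefficient to profile; the orderings (which schedule is best,
which is worst, ratios between schedules, sensitivity rankings across decay
rates) are robust across the `lambda_S2` values we examined, the absolute
rates are not.

## Initial conditions

The experiments start from the resting state of an untreated cell: the
intracellular variables at the stable Pt equilibrium computed at $S = 0$,
$J = J_s/\mu_J = 1$, no drug on board, and initial tumour volume
$T(0) = 0.1$ (`default_initial_state()`). The tumour value is our choice
(the protocols do not state one) and is pinned by the optimal-control
convention that the desired volume $\bar T = 1.7634$ equals half the
untreated volume at the end of the 30-unit horizon: a pure logistic run with
$r = 0.12$, $T_0 = 100$ reaches $2\bar T = 3.527$ at $t = 30$ exactly when
$T(0) \approx 0.1$. With $T(0) \ll T_0$ the tumour stays in the
near-exponential regime, so normalized volumes (treated over control) are
insensitive to the exact $T(0)$.

## Numerics

*Integration.* The eight-state system has a discontinuous right-hand side
(the indicator $I$). `simulate_model()` uses a fixed-step classical RK4
written in C++ with sub-steps no longer than `dt_max` (default $2\times
10^{-3}$), with every edge of a piecewise-constant infusion placed exactly
on a grid node, so each step integrates a smooth-in-time field and the
indicator discontinuity contributes a local $O(\Delta t)$ error confined to
the switching step. States are clamped at 0 (they are provably non-negative;
the clamp removes roundoff excursions). On smooth stretches the integrator
agrees with `deSolve::lsoda` at tolerance $10^{-10}$ to $\sim 10^{-10}$
(tested), and the IFN-beta compartment reproduces its closed-form
exponential to $10^{-6}$.

*Equilibria.* In the intracellular subsystem, STAT3, Bcl-2 and BAX each
appear only linearly in their own balance, so every equilibrium reduces to a
root of one scalar function of STAT1. `find_equilibria()` brackets its sign
changes on a 4001-point grid over $[0, 20]$ and polishes each root with
`uniroot` — complete for this structure and fast enough to scan. A
structure-agnostic damped-Newton solver started from 150–200 Latin-hypercube
points (`method = "multistart"`, analytic Jacobian) is kept as the
independent cross-check; the two agree to $10^{-4}$ on the scanned grid
(tested). Stability comes from the analytic 4×4 Jacobian: stable if the
leading eigenvalue real part is below $-10^{-8}$, unstable above $+10^{-8}$,
marginal in between (the band avoids misclassification at folds). Fold
points are refined by bisection on the equilibrium count to $10^{-4}$ in
$S$.

*Hysteresis sweeps.* Rather than integrating an explicitly time-dependent
system, `hysteresis_sweep()` imposes the ramp exactly through the
feed-forward infusion $u_S(t) = \dot S_{des} + \mu_S S_{des}(t)$ and pins
JAK2 the same way, reusing the main integrator. Ramp-rate matters: the
escape from a disappearing branch lags the fold (delayed loss of stability,
scaling like rate$^{2/3}$); at rate $3\times10^{-5}$ the transitions land
within $0.006$ of the fold points.

*Forward–backward sweep.* The optimal dosing problems minimize
$\int A_1 (T-\bar T)^2 + A_2 B^2 - A_3 X^2 + C_1 u_S + C_2 u_D + C_3 u_S^2 +
C_4 u_D^2 \, dt$ by Pontryagin's conditions: forward state solve, backward
adjoint solve with zero terminal costate, pointwise control update $u_S^* =
\mathrm{clip}((-C_1 - \lambda_S)/(2 C_3),\, 0,\, u_S^{max})$ (analogously
for cisplatin), and relaxed acceptance. The adjoint system is derived
analytically from the Hamiltonian and checked against central differences
(worst error $\sim 10^{-8}$, tested). Two treatments of the indicator are
provided. In `"hard"` mode the forward pass uses the discontinuous switch
and the adjoint freezes the indicator at its forward values; in `"smooth"`
mode (the optimization default) both passes use the product-of-sigmoids
relaxation with steepness `smooth_k = 100`, keeping the control-to-state map
differentiable. The hard mode turns out to limit-cycle on these problems —
near-threshold trajectories graze the switching surface, so arbitrarily
small control changes flip long kill windows and the sweep oscillates
regardless of relaxation — which is why the smooth mode is the optimization
default. Convergence is declared on the *unrelaxed* fixed-point residual
(relative L1 distance between the controls and their stationarity update,
tolerance $10^{-3}$), so a shrinking relaxation cannot fake convergence; the
relaxation factor itself adapts (halved on objective increase, regrown 10%
on success from an initial 0.5, floor $2\times10^{-3}$). The running cost is
indefinite ($-A_3X^2$), but the compact control box and finite horizon bound
the objective; the iteration log records objective, residual and relaxation
per sweep. Because the whole-horizon problem's only gradient path to
"killing" runs through the indicator — flat far from the switching surface —
a zero initial control is itself stationary; `run_strategy_I()` therefore
initializes at the constant reference profile (scaled with $\mu_S$ so the
initial steady drug level is invariant when the decay rate is varied).

## The experiment layer

`pulse_schedule()` encodes an ordering string over {S, D} (one drug per
5-unit slot, on-interval $[t_i, t_i + h)$, half-open so abutting pulses
never overlap). The minimum-dose search bisects the infusion rate until the
final tumour volume is 50% of the *no-IFN-beta* control — the control run
keeps the same cisplatin pulses and zeroes only $u_S$, matching the
experiment's naming of IFN-beta alone as the varied agent; a fully untreated
control is available as an option. The resting-time search bisects the
on-duration $h_s$ at fixed rate (default 8.2, the rate of the
20-schedule comparison; the protocols do not print the rate used, so it is
an argument). Pulsed monotherapy (`dose_response()`) uses onsets at
$t = 1, 3, 5, 7, 9$ with width 1 — half the onset spacing; the width is
not stated in the protocols, and with it the infusion is genuinely pulsatile
rather than effectively continuous. Fixed-total experiments rescale the rate
as total$/(N h)$ so the delivered dose is exactly invariant in $h$.

For the whole-horizon comparison, the alternating profile (IFN-beta every 4
units at rate 5.2344, cisplatin every 2 units at rate 53.4109) uses pulse
widths chosen so its delivered totals equal the constant profile's
($4.1875 \times 30 = 125.6256$ and $24.9251 \times 30 = 747.753$) exactly;
the on-times (24 and 14 of 30 units) are the one free choice, since only the
rates and periods are specified. The optimal run's delivered totals are
reported and flagged when they differ from the references by more than 1% —
no isoperimetric constraint is imposed.

## What the packaged experiments do and do not show

The packaged configurations (`run_experiment("fig4")`, … `"fig12"`)
regenerate every quantity from the model itself; nothing is read from
external data. They demonstrate the mechanism — the bistable switch, the
JAK2 veto, why contiguous early IFN-beta dosing beats scattered dosing, and
what optimal control buys in dose efficiency and robustness to the IFN-beta
half-life. They do not validate the model against measured tumour-growth
data, and the absolute dosing scale carries the `lambda_S2` uncertainty
described above. Simulated experiments in the test suite use slightly
coarsened grids (`dt_out = 0.02`, `dt_max = 0.005`, hysteresis ramps at
$10^{-4}$–$3\times10^{-5}$, multi-start with 150 points) chosen so the whole
suite re-derives the bifurcation structure, the schedule orderings and the
optimal-control certificates in a few minutes on one core; the packaged
defaults are one notch finer.

## Degenerate inputs and tie-breaks

Boundary states ($B = B_{th}$ or $X = X_{th}$) classify as indicator-off and
phase-"neither" (strict inequalities). A single-point bifurcation scan
returns that point's equilibria with a degenerate (zero-width) window.
`max_resting_time()` returns rest 0 with `feasible = FALSE` when even
continuous infusion misses the target, and the full slot at target fraction
1. Equilibria closer than $10^{-6}$ in Euclidean distance are merged;
branches are labelled lower/middle/upper by STAT1 ordering.
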