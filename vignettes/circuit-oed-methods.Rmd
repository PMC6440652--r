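---
title: "Methods: Fisher-information optimal design for synthetic gene circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Fisher-information optimal design for synthetic gene circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuitOED)
```

## The modeling problem

`circuitOED` studies how to *design* induction experiments for two
benchmark synthetic gene circuits so that their kinetic parameters can be
estimated as precisely as possible at the lowest measurement cost.  Both
circuits are induced by the small molecule doxorubicin (DOX) and read out
through a GFP reporter expressed from the synthetic promoter P_TR-SSRE;
the only measured quantity is the fluorescence trajectory, which is the
typical experimental constraint for this class of circuits.

The **unbuffered** circuit is the direct design: DOX drives production of
the transcription factor SKN7m (state `Xm`, Hill kinetics with
coefficient `n1` and half-saturation `K_dox`), SKN7m binds the promoter
reversibly (`k_on`, `k_off`) forming the complex `Cm`, and free SKN7m
activates GFP (`G`) through a second Hill term (`n2`, `K_gfp`).  Complex
turnover (`delta_C`) releases SKN7m back.  Three states, nine kinetic
parameters (the promoter-site total `p_T` is treated as part of the
estimated kinetic vector in this circuit, which is what makes the count
nine; in the buffered circuit it is a fixed constant).

The **buffered** circuit inserts a phosphotransfer driver module between
induction and reporter: DOX induces the STAT5-HKRR fusion (`Z`), whose
phosphoform (`Zs`) passes phosphate through the YPD1 relay (`WT`, active
form `Ws`) onto SKN7 (`XT`; singly and doubly phosphorylated forms `Xs`,
`Xss`).  Doubly phosphorylated SKN7 activates GFP and binds promoter and
load sites (`Cs`, `Css`).  Retroactivity of downstream load on the driver
enters through the constants `r1`, `r2`.  Ten states, twenty-three
kinetic parameters, with the biologically motivated constraints
`k1 >= k3`, `k2 >= k4` and `k1..k4` within [1, 50] 1/(uM min) enforced at
construction.  Genetic load (extra promoter copies) is modeled as a
multiplier `load_factor` in {1, 2, 3} on `p_T`.

Units are minutes and uM throughout.

## Default parameters and the regime they encode

No reference parameter values exist for these circuits in the form the
package needs, so the defaults shipped in `default_params()` are
*repository defaults*: a single documented choice, not measurements.
They were fixed once, at design time, by three requirements:

1. **Responsiveness over the feasible induction range.**  With
   `K_dox = 25` (uM^2, Hill coefficient 2) the half-maximal response sits
   near 5 uM, so the steady GFP output varies several-fold over the
   design interval [1, 30] uM rather than saturating at its edge.
2. **A reporter Hill term near half-saturation** (`K_gfp` matched to the
   operating range of free SKN7m, resp. doubly phosphorylated SKN7), so
   GFP actually transmits upstream parameter perturbations.
3. **A binding regime that is both sign-structured and identifiable.**
   Binding and complex turnover (`k_on = 0.2` 1/(uM min),
   `k_off = 0.02`, `delta_C = 0.02` 1/min) are deliberately *slow*
   relative to SKN7m production and decay.  In this regime the transient
   sequestration of free SKN7m by promoter binding makes the GFP
   sensitivity to `k_on` non-positive and to `k_off` non-negative over
   the whole response window, and -- equally important -- it keeps the
   two rates separately identifiable from sampled fluorescence.  A
   fast-equilibrating complex would collapse the two onto their ratio
   (sensitivity-column correlation near -1, Fisher condition number in
   the thousands), making any recovery experiment ill-posed.  This is a
   property of the regime, not of the estimator.

Initial conditions are zero for all species except the buffered totals
`WT(0) = k_w / delta_W` and `XT(0) = k_x / delta_X`, their unforced
steady states; starting the relay pools anywhere else would superimpose a
production transient unrelated to the input onto every designed
experiment.

## Inputs and simulation

Input signals (`make_input()`) are deterministic step, double-step,
square (50% duty cycle, high phase first, so stimulation begins at
t = 0) or constant waveforms.  Trajectories are integrated with the
stiff-capable `deSolve::lsoda` at `rtol = 1e-8`, `atol = 1e-10` by
default; the integration is restarted at every input discontinuity so
square-wave edges are resolved exactly rather than smeared by step-size
control.  The solver-accuracy contract -- halving `rtol` moves the GFP
trajectory by less than 1e-6 relative -- is part of the test suite.
Non-negativity is respected to solver tolerance; values are not clipped.

## Sensitivities, Fisher information, and design criteria

Local parameter sensitivities s(t) = dx(t)/dp are computed by the forward
sensitivity equations ds/dt = Jx s + Jp with s(0) = 0.  Both Jacobians
are generated *symbolically* (`stats::D` applied to the same expression
lists that define the right-hand sides) and compiled once per circuit,
so there is no truncation error beyond the integrator's own.  The
initial state is treated as a fixed experimental condition, evaluated at
the reference parameters; this convention is what makes s(0) identically
zero and is applied consistently in the central finite-difference
fallback (relative step 1e-5, absolute floor 1e-8), which serves as the
independent cross-check.  When comparing the two routes, both must be
integrated tightly (about `rtol = 1e-11`): a difference quotient with
step 1e-8 amplifies solver noise at the default tolerance by orders of
magnitude, which is a property of finite differences and not of the
sensitivity system.

From the observable rows of the sensitivity tensor and the per-point
measurement standard deviations, `fisher_information()` assembles
F = sum_i S(t_i)^T diag(1/sigma_i^2) S(t_i).  Its inverse diagonal gives
the per-parameter Cramer-Rao variance bounds; eigenvalues give the four
scalar criteria (A = trace of the inverse, D = determinant, E = smallest
eigenvalue, and the modified E-criterion modE = lambda_max/lambda_min,
the condition number, whose ideal value is 1).  F counts as numerically
singular when lambda_min/lambda_max < 1e-12; in that case parameters
aligned with the null space are reported with infinite bounds and a
non-identifiability warning rather than a misleading finite number.
Bounds are reported as variances; the tidy view adds the square-root
standard-deviation column.

## Measurement model

Synthetic measurements (`generate_measurements()`) sample the GFP
trajectory at evenly spaced times and add independent Gaussian noise
with sigma_i = max(sigma_rel |y_i|, sigma_floor); defaults are 5%
relative with a 1e-3 uM floor -- again repository defaults, chosen as a
plausible fluorescence noise level.  The recorded sigma_i are the single
source of truth downstream: the same values weight the residuals in
estimation and the Fisher matrix in design, so the accuracy analysis is
consistent with the data-generating process.  Negative noisy values are
kept by default so the Gaussian assumption (and the chi-squared
goodness-of-fit calibration that relies on it) holds exactly; a clipping
option exists for realism at the cost of that exactness.

## Estimation objectives and goodness of fit

The error indexes are the root-mean-square error and the
sigma-weighted residual sum of squares (wRSSE), the latter following a
chi-squared distribution with n - p degrees of freedom under the true
model, which yields the GOF p-value.  QQ diagnostics use plotting
positions (i - 0.5)/n.  The sample-size objective is

J(n_m) = sum of squared residuals + lambda (n_m - n_p)/n_m,

an accuracy term plus a normalized measurement-cost penalty (lambda
defaults to 0.8).  The accuracy term uses *raw* squared residuals by
default; because a reasonable alternative reading weights them by the
measurement sigmas, that variant is available behind the
`weighted` flag, with the raw form kept as the default.

## Optimizers

Harmony search is the package's workhorse: a memory of `hms = 15`
candidate vectors; each improvisation draws every coordinate from the
memory with probability `hmcr` (presets 0.2 for small problems and 0.8
for the nested design loop), pitch-adjusts it with probability
`par = 0.2` by up to 5% of the box width, or redraws it uniformly; the
candidate replaces the worst memory row only on strict improvement, so
the incumbent-best trace is monotone.  The pitch rate and bandwidth are
common harmony-search settings, exposed in `hs_config()`.  The
real-coded GA baseline uses tournament selection, arithmetic crossover
and Gaussian mutation with rates mutation 0.8 / crossover 0.2 as used in
the package's comparisons (conventional GA practice often reverses the
two; both knobs are exposed), elitism of one.  The PSO baseline is
global-best with inertia weight 1, c1 = c2 = 1, velocities clamped to
half the box width.  All three are seeded and bit-reproducible.

## The nested design loop

`outer_design()` implements the two-stage loop.  The outer harmony
search proposes induction levels u in [1, 30] uM.  Each candidate is
scored by generating synthetic measurements under u, fitting the free
parameters by an inner harmony search (wRSSE objective; the current
incumbent estimate seeds the inner memory), and evaluating the modified
E-criterion of the Fisher matrix at the fitted parameters.  The inner
fitness is the estimation error and the outer fitness the information
balance; a combined outer criterion (modE plus wRSSE) is available via
the `combine` flag.  The incumbent pair (u*, p*) moves only on strict
criterion improvement, and ties keep the earlier candidate everywhere.

Two numerical choices matter here.  First, the measurement seed for a
candidate u is derived deterministically from the master seed and u
rounded to 0.01 uM, so the outer objective is a *deterministic function
of u*; without this, harmony-memory comparisons would be dominated by
noise realizations rather than design quality.  Second, simulation
failures and singular Fisher matrices score +Inf, so infeasible
candidates are discarded by the strict-improvement rule rather than
crashing the loop.  `screen_input_levels()` runs the same scoring over
an explicit grid with the same per-u seeds and serves as the brute-force
reference: on small problems the nested search should land within one
grid step of the screened optimum.  Because modE >= 1 for any
non-singular Fisher matrix, fitness traces are reported raw, and any
normalized view is left to plotting.

`select_sample_size()` sweeps candidate sample sizes (default 10 to 100
in steps of 10), refits the parameters at each, and minimizes J(n_m).
With noiseless data and the truth supplied as the incumbent, the
accuracy term vanishes identically and the objective reduces to its
strictly increasing penalty, so the smallest admissible size is selected
-- a useful degenerate check that the machinery adds nothing spurious.

## Problem sizes used by the tests and the acceptance script

The shipped checks run on deliberately compact designs chosen as the
package's own verification sizes: recovery experiments use a 20 uM step,
25 samples over 600 minutes and a 2000-improvisation inner search;
screening equivalence uses a 7-point grid over [1, 30] uM with 20
samples per candidate and a 150-improvisation inner budget; buffered
sensitivity cross-checks use a 300-minute window.  These sizes keep each
property sharp (the quantities compared are scale-free) while keeping a
full verification run in the minutes range.

## Known limitations

* Sensitivities are local; no global (Sobol/Morris) indices.
* The model is deterministic; intrinsic expression noise is represented
  only through the additive measurement model.
* The outer criterion landscape is rugged because each candidate u
  carries its own finite inner-fit budget; the screening oracle is the
  honest reference on coarse grids, and larger inner budgets smooth the
  landscape at linear cost.
* Whether the retroactivity terms `r1`, `r2` are constants or
  load-dependent is an open modeling question; they are implemented as
  constants.
* The synthetic measurement generator emulates sampled fluorescence with
  independent Gaussian noise; real plate-reader data carry correlated
  drift, background subtraction artifacts and calibration error that
  this stand-in does not represent, so passing tests certify the
  method's internal consistency, not instrument-level robustness.
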