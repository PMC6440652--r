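# circuitOED

Fisher-information optimal experimental design (OED) for two benchmark
synthetic gene circuits, with a harmony-search estimation engine.

## The problem

Synthetic gene circuits induced by a small molecule (here doxorubicin,
DOX) and read out through a GFP reporter are routinely modeled as ODE
systems, but the kinetic parameters of those models must be inferred
from sparse, noisy fluorescence time courses.  How strongly the data
constrain the parameters depends on the *experiment*: the induction
level, and how many time points are measured.  `circuitOED` is for
modelers of such circuits who want to pick those design variables
deliberately rather than by habit.

The package covers the full loop:

* **Circuits** — the *unbuffered* reporter circuit (DOX → SKN7m →
  promoter binding → GFP; 3 states, 9 kinetic parameters) and the
  *buffered* variant with a phosphotransfer driver module that insulates
  the reporter from genetic load (10 states, 23 kinetic parameters,
  retroactivity constants `r1`, `r2`), in minutes/uM units, simulated
  with a stiff-capable solver under step, double-step or square-wave
  inputs.
* **Sensitivities** — forward sensitivity equations
  `ds/dt = Jx s + Jp` with symbolically derived Jacobians, plus a
  finite-difference cross-check.
* **Information analysis** — the Fisher information matrix
  `F = Σ Sᵀ diag(1/σ²) S`, Cramér–Rao variance bounds `diag(F⁻¹)`, and
  the A-, D-, E- and modified-E (`λ_max/λ_min`, the condition number)
  design criteria.
* **Design** — a two-stage nested loop: an outer harmony search over
  the induction level u ∈ [1, 30] uM scored by the modified-E
  criterion, an inner harmony search fitting the parameters by weighted
  least squares under each candidate; plus a sample-size rule
  `J(n_m) = Σ(yᵢ − ŷᵢ)² + λ (n_m − n_p)/n_m` trading accuracy against
  measurement cost, and GA/PSO baselines for comparison.
* **Synthetic data** — reproducible Gaussian-noise measurements
  (`σᵢ = max(σ_rel |yᵢ|, σ_floor)`) standing in for wet-lab
  fluorescence.

Everything tabular comes back as a tibble; fitted objects have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Recover the promoter binding rates of the unbuffered circuit from a
designed experiment, then ask how well that experiment constrains them:

```r
library(circuitOED)

mod <- circuit_model("unbuffered")
mod
#> <circuit_model> unbuffered circuit: 3 states, 9 kinetic parameters (load x1)

u <- make_input("step", magnitude = 20)      # 20 uM DOX step
meas <- generate_measurements(mod, u, n_m = 25, t_f = 600,
                              noise = noise_model(0, 0), seed = 5)

fit <- inner_estimate(mod, u, meas, free = c("k_on", "k_off"),
                      config = hs_config(max_iter = 2000, seed = 11))
round(fit$par, 4)
#>   k_on  k_off
#> 0.2001 0.0200      # truth: 0.20, 0.02 — recovered to ~0.1%

S   <- forward_sensitivities(mod, u, meas$time, free = c("k_on", "k_off"))
fim <- fisher_information(S, pmax(0.05 * abs(attr(meas, "truth")), 1e-3))
glance(fim)
#>       A     D     E  modE lambda_max lambda_min singular
#> 1 0.104 8520.  9.71  90.3       877.       9.71 FALSE
tidy(fim)
#>   parameter   crlb crlb_sd
#> 1 k_on      0.0865   0.294
#> 2 k_off     0.0176   0.133
```

Read: from 25 samples of a 600-minute, 20 uM step experiment at 5%
measurement noise, no unbiased estimator can beat standard deviations of
about 0.29 for `k_on` (value 0.2) and 0.13 for `k_off` (value 0.02) —
the binding rates lie on a correlated ridge (modE ≈ 90), which is
exactly the kind of diagnosis that motivates optimizing the design.
`outer_design()` then searches the induction level that minimizes modE,
`select_sample_size()` the number of samples worth paying for, and
`autoplot()` on any of the results draws the corresponding picture.

A thin CLI wraps the same functions after installation:

```sh
circuit-oed simulate --model buffered --out-dir out/
circuit-oed oed --config my_run.yaml --seed 3 --out-dir out/
```

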