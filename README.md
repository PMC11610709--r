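# telsurv

Joint habitat-selection inference from animal telemetry and spatial
snapshot-survey data.

## The problem

Spatial ecologists estimate habitat selection from two very different
kinds of data. Telemetry follows individual animals through time and is
usually analyzed with step-selection models; spatial surveys (transects,
grid counts, one-off censuses) record where animals are at an instant and
are analyzed with habitat-selection / point-process models. The two
frameworks do not, in general, estimate the same quantity, which has kept
the data types apart.

`telsurv` implements a joint likelihood that makes them compatible. Space
use is a log-linear utilization surface

π(x) ∝ exp{η(x)},  η(x) = β₁c₁(x) + … + β_k c_k(x),

and each animal moves as a **Langevin diffusion** whose stationary
density is exactly π:

dx = (Γ/2) ∇log π(x) dt + √Γ dW.

Telemetry fixes then contribute Euler–Maruyama Gaussian steps (with a
locally **averaged drift** that removes most of the discretization bias
of the naive likelihood), a snapshot survey over a region A contributes
an **inhomogeneous Poisson** likelihood with intensity exp{α + η(x)},
and the two log-likelihoods simply add because they share β:

L(α, β, γ) = L_s(α, β) + L_M(β, γ),  γ = log Γ.

The package provides the full workflow: gridded-covariate handling
(bilinear values and gradients, ESRI ASCII I/O), Gaussian-random-field
landscape simulation, Ornstein–Uhlenbeck central-attraction localization
expressed as three polynomial covariates, vectorized colony simulation,
maximum-likelihood fitting (L-BFGS-B with analytic gradients and
Hessian-based standard errors), and replicated simulation experiments
for deciding how to split field effort between tracking and surveying.

## Worked example

```r
library(telsurv)
set.seed(1)

# a resource landscape: exponential-covariance Gaussian random field
field <- simulate_grf(range = 0.1, variance = 0.1, seed = 42)

# habitat model: selection on the field plus central attraction
ou <- ou_attraction_model(mu = c(0, 0), lam = 0.2^2)
truth <- habitat_model(c(list(field), ou$covariates), c(2.0, ou$beta))

# telemetry: 20 tracked individuals, fixes at unit intervals
starts <- matrix(rnorm(40, 0, 0.05), 20, 2)
tracks <- simulate_colony(truth, Gamma = 1e-5, starts, fine_step = 0.1,
                          duration = 500, obs_interval = 1, seed = 7)

# snapshot survey of a 100-strong colony on a centred square
grid <- eval_grid(-1, 1, -1, 1, 0.005)
snap <- sample_colony_snapshot(truth, 100, grid, square_region(0.5),
                               seed = 8)
snap
#> <survey_snapshot> m = 62 points over area 0.25

# joint maximum-likelihood fit with the 4-point averaged drift
fit <- fit_joint(tracks, snap, truth$covariates, scheme = "g4",
                 grid = grid)
fit
#> <joint_fit> converged  loglik = 87005.630
#>   estimates:
#>     alpha        5.88532  (se 0.2294)
#>     beta1        1.78465  (se 0.2766)
#>     beta2      -0.951628  (se 0.8798)
#>     beta3      -0.515061  (se 1.042)
#>     beta4        15.8608  (se 10.74)
#>     gamma       -11.5096  (se 0.009995)

fit_precision(fit, "beta1")
#> [1] 13.06713
```

What the numbers mean: `beta1` is the selection coefficient of the
resource field (generative value 2.0; the estimate sits within about one
standard error of it). `beta2`–`beta4` are the localization nuisance
coefficients — `beta4` is the inverse home-range variance, weakly
identified from tracks that have not yet explored the whole home range,
which is why its standard error is large. `alpha` scales the expected
survey count (here 62 detections on a 0.5 × 0.5 square) and `gamma` is
the log diffusivity (truth log 1e-5 ≈ −11.51, pinned down very precisely
by 10 000 telemetry steps). The reported precision 1/se² of `beta1` is
the quantity the effort-allocation experiments optimize.

Higher-level experiment drivers: `bias_study()` (raw vs averaged drift
on shared datasets), `run_experiment()` (replicated factorial designs
over track numbers and survey sizes), `fit_precision_surface()` +
`effort_curve()` (smooth precision summaries and optimal effort splits),
`additivity_check()` (joint precision vs sum of single-source
precisions). A thin command-line wrapper is installed at
`system.file("cli", "telsurv.R", package = "telsurv")` with subcommands
`fixtures`, `simulate-landscape`, `simulate-tracks`, `simulate-survey`,
`fit`, `bias-study` and `experiment`.

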