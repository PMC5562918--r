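# npfilter

Weight-free particle filtering and online parameter learning for
continuous-time nonlinear state-space models.

## The problem

Many estimation problems in computational neuroscience and signal
processing are *filtering* problems: a hidden diffusion

&nbsp;&nbsp;dx_t = f(x_t) dt + Σ_x^{1/2} dw_t

is observed only through noisy increment observations

&nbsp;&nbsp;dy_t = g(x_t) dt + Σ_y^{1/2} du_t,

and the posterior p(x_t | y_{0:t}) must be tracked online.  Weighted
(bootstrap) particle filters solve this generically but suffer weight
degeneracy: the number of particles required grows exponentially with the
hidden dimension (the curse of dimensionality), and importance weights
have no plausible neuronal implementation.

`npfilter` implements an **unweighted particle filter**: N equally
weighted particles z^(k) follow

&nbsp;&nbsp;dz^(k) = f(z^(k)) dt + W_t (dy_t − g(z^(k)) dt) + Σ_x^{1/2} dω^(k),

where the gain W_t = cov(z, g(z)) Σ_y^{−1} is estimated from the ensemble
itself each step (or learned online).  Each particle is corrected directly
by its own innovation, so there are no weights to collapse, and posterior
expectations are plain particle averages.  This is the filter-as-neuronal-
dynamics picture: particles are "filtering neurons", innovations are
"novelty neurons", W is a decoding weight matrix.

The package also provides:

* an Euler–Maruyama simulator and a model zoo (double-well dynamics with
  linear *visual* and sigmoidal *auditory* channels; d-dimensional OU and
  double-well families for scaling studies), with stationary-density
  helpers;
* reference filters: exact Kalman–Bucy, weighted bootstrap particle filter
  with systematic resampling, and the averaged-prediction (EnKBF /
  constant-gain feedback) particle update;
* online maximum-likelihood learning of the generative weight J and the
  gain W by gradient ascent on the observation log-likelihood, with the
  filter derivative tracked by exact forward sensitivity propagation, plus
  the local Hebbian small-noise approximation;
* benchmark drivers: time-averaged MSE, particles-needed-versus-dimension
  searches, and linear/exponential scaling-law fits with AIC comparison;
* a JSON-configured command line (`inst/cli/npf.R`).

## Worked example: multisensory tracking

A double-well "prey" trajectory is tracked through a linear visual channel
and a sigmoidal auditory channel (sensory noise 0.1 each):

```r
library(npfilter)
model <- model_zoo("frog")                       # n = 1 hidden, m = 2 channels
rec   <- simulate_ssm(model, T = 50, dt = 0.01, seed = 1)
run   <- run_filter(model, rec, N = 1000, seed = 1)

time_averaged_mse(run$xhat, rec$x)
#> [1] 0.1479
run$W_mean
#>       [,1]  [,2]
#> [1,] 1.248 0.944
```

The tracking MSE, 0.148, matches a 10,000-particle weighted bootstrap
filter on the same record (0.149) — near-optimal accuracy from 1000
weight-free particles.  The time-averaged gains show both channels in
use: the visual gain ≈ var(x)/σ_v² and the auditory gain is scaled by the
sigmoid's slope, so audition counts most when the posterior sits between
the wells.  Branch certainties (fraction of particles near each well) and
per-step gain traces are in `run$certainty` and `run$W_trace`.

On the linear reference family the exact optimum is known:
`riccati_steady(-0.75)` returns `0.5`, the steady-state Kalman–Bucy MSE
per dimension, which normalizes all scaling-study ratios.

## Command line

```sh
Rscript inst/cli/npf.R simulate      --config cfg.json --out sim.csv
Rscript inst/cli/npf.R filter        --config cfg.json --out track.csv
Rscript inst/cli/npf.R learn         --config cfg.json --out learn.csv
Rscript inst/cli/npf.R frog-demo     --config cfg.json --out demo.csv
Rscript inst/cli/npf.R bench-scaling --config cfg.json --out scaling.csv
```

Configs are JSON (`model`, `sim`, `filter`, `learning`, `scaling`
sections); every CSV gets a JSON sidecar embedding the resolved config and
its hash, so runs are reproducible from (config, seed) alone.  A ready
example lives at `inst/extdata/frog-config.json` (it reproduces the worked
example above: `filter` on it reports MSE 0.1479).

## Design notes

See `vignettes/npfilter-methods.Rmd` for the model assumptions, the
analytic fixed point of the ensemble gain (and how it differs from the
Kalman gain), the choice of observation noise in the scaling families,
learning-rate choices, degenerate-input behavior, and known limitations.
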