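# sindypi

Data-driven discovery of **implicit dynamical systems and
rational-function nonlinearities** from time-series and
spatio-temporal measurements, in R.

Saturating enzyme kinetics, coupled rigid-body mechanics and
Hill-type metabolic regulation all have right-hand sides of the form
`xdot = N(x) / D(x)`. Such dynamics are not a sparse combination of
library terms, so ordinary sparse regression (regressing `xdot` on a
candidate library) cannot represent them. Cleared of denominators they
become *implicit* relations `f(x, xdot) = 0`, and the classical
implicit approach — finding the sparsest vector in the null space of
an extended library `Theta(X, Xdot)` — is notoriously fragile to
noise.

This package implements the robust, parallel alternative: every
candidate term is tested in turn as a known left-hand side,

```
theta_j(X, Xdot) = Theta'(X, Xdot) xi_j     (column j removed),
```

each candidate yielding an ordinary sparse regression solved by
sequentially thresholded least squares. Correct candidates produce
sparse, accurate models that rediscover one another's supports;
incorrect candidates produce dense, inaccurate ones. Model selection
scores every candidate on held-out data by predicted-derivative error
`||Xdot_t - N(x_t)/D(x_t)|| / ||Xdot_t||`, cross-references the
rediscovered supports, and returns the winning implicit relation in
explicit rational form.

Included alongside the core method:

* the null-space/ADM baseline (`adm_implicit_sindy`) and a constrained
  joint formulation with exactly zero diagonal
  (`constrained_joint_solve`);
* an explicit PDE regression baseline (`pdefind_baseline`) and
  implicit PDE identification with `u_t`-bearing libraries
  (`fit_pde_implicit`);
* total-variation regularized differentiation for noisy signals
  (`tvreg_diff`), matrix-free for long records;
* seeded simulators for every benchmark system: Michaelis–Menten
  kinetics, the seven-state yeast glycolysis oscillator, a forced
  cart-pendulum, a mounted double pendulum, a modified KdV equation
  with a rational gain term (spectral ETDRK4), and a simplified
  Belousov–Zhabotinsky reaction–diffusion model;
* reproducible noise-robustness and data-efficiency benchmarks
  comparing the candidate sweep with the null-space baseline.

## Worked example: enzyme kinetics

Simulate the substrate model `xdot = jx - Vmax*x/(Km + x)` with
`jx = 0.6`, `Vmax = 1.5`, `Km = 0.3`, build the degree-2 implicit
library `{1, x, x^2, dx, x*dx, x^2*dx}`, sweep the derivative-bearing
candidates over a threshold grid, and select on a held-out block:

```r
library(sindypi)

data <- simulate_michaelis_menten(mm_params(), x0 = 0.5,
                                  times = seq(0, 10, by = 0.001))
rep <- sindy_pi(data, mm_library_spec(), lambdas = seq(0.1, 1, by = 0.1))
rep$winner
#> <candidate_model> lhs = dx, lambda = 0.9, 3 active terms, rel. residual = 7.07e-08
#>   1                        +0.6
#>   x                        -3
#>   x*dx                     -3.33333
```

The winning implicit relation `dx = 0.6 - 3x - 3.333*x*dx` rearranges
exactly into rational form, and normalizing the denominator's linear
coefficient reads off the kinetic constants:

```r
ode <- normalize_rational(rep$winner_ode, by = "x")
ode
#> <rational_ode> dx/dt = N/D
#>   N: +0.18*1 -0.9*x
#>   D: +0.3*1 +1*x
Km <- rational_coef(ode, "1", "den")      # 0.3000002  -> Km
jx <- rational_coef(ode, "1", "num") / Km # 0.5999997  -> jx
jx - rational_coef(ode, "x", "num")       # 1.5000000  -> Vmax
```

All three constants are recovered to about one part in 10^6 from the
noise-free trajectory. `simulate_identified()` integrates the
recovered rational model; its trajectory deviates from the true one by
less than 1e-8 over the full horizon.

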