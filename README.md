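# cellfate

Tools for quantifying stochastic cell-fate decisions in cultured cell
populations observed as daily counts of proliferating (P), differentiated
(D) and dead (N) cells — the classic design for growth-factor studies in
PC12-like neuronal model systems, where EGF drives proliferation, NGF
drives differentiation, and the surrounding serum level tunes how
heterogeneous the population becomes.

The package implements, end to end:

* **A three-state Markov transition model.** Each cell carries five
  constant intensities (1/day): proliferation α (P → 2P), differentiation
  β (P → D), de-differentiation γ (D → P), and the death rates d₁, d₂.
  Mean densities follow a linear ODE system whose living block
  `A = [[α−β−d₁, γ], [β, −(γ+d₂)]]` is a Metzler matrix, so the spectrum
  is real: the phase portrait is a stable node (extinction) or a saddle
  (growth), and the dominant eigenvalue λ_M — the Malthus coefficient —
  is the asymptotic per-day growth rate of the surviving population.
  Closed-form eigen-solutions, numeric integration, and phase-portrait
  classification: `analytic_solution()`, `solve_ode()`,
  `malthus_coefficient()`, `classify_critical_point()`.
* **Heterogeneity and response metrics.** Shannon entropy of the fate
  fractions (0 to ln 3), initial and time-averaged net fluxes, ratio- and
  difference-normalised growth-factor response indices, Cohen's d and η²:
  `shannon_entropy()`, `entropy_timecourse()`, `initial_flux()`,
  `mean_flux()`, `response_indices()`, `cohens_d()`, `eta_squared()`.
* **Bayesian rate estimation from population time courses.** A Gaussian
  observation model on image counts, independent gamma priors, and
  random-walk Metropolis–Hastings under a four-phase simulated-annealing
  schedule (explore, sample at temperature 1, cool, exploit), with the
  estimate averaged over the phase-4 best-likelihood sets:
  `run_annealed_mcmc()`, `log_likelihood()`, `log_posterior()`.
* **Exact stochastic simulation and Taylor's power law.** A compiled
  Gillespie sampler of the five-reaction scheme with an absorbing
  boundary at zero living cells, four model variants crossing
  constant/truncated-normal rates with constant/lognormal initial counts,
  mean–variance (V = a·M^b) fitting, lognormality diagnostics, and
  closed-form birth–death moments as an analytic oracle:
  `gillespie_run()`, `simulate_ensemble()`, `fit_powerlaw()`,
  `fit_lognormal()`, `birthdeath_moments()`.
* **A study-shaped synthetic-data generator** (3 serum levels × control/
  EGF/NGF, daily counts, 30 fields per dish, 4 replicates) with known
  ground truth, plus a config-driven pipeline writing tidy CSV/JSON
  artifacts and a reproducibility manifest: `generate_dataset()`,
  `preset_conditions()`, `run_pipeline()`.

## Worked example

Simulate a high-serum-like culture, estimate its rates back from the
counts, and summarise the population dynamics:

```r
library(cellfate)

p <- rate_params(alpha = 0.6, beta = 0.05, gamma = 0.2, d1 = 0.05, d2 = 0.05)
malthus_coefficient(p)
#> [1] 0.5131044        # 1/day: doubling time ~1.4 days
classify_critical_point(p)
#> Critical point: saddle (eigenvalues 0.5131, -0.2631; discriminant 0.6025)

# a one-condition synthetic experiment (30 fields/day, days 0-7)
ds <- generate_dataset(
  study_design(conditions = data.frame(serum = "high", stimulus = "control"),
               replicates = 1),
  ground_truth(p), mode = "ode_noise", seed = 1)

fit <- run_annealed_mcmc(ds$counts, obs = observation_model(C = ds$C),
                         seed = 42, mode = "per_field")
fit
#> Annealed-MCMC rate estimate (1/day):
#>  alpha   beta  gamma     d1     d2
#> 0.5953 0.0385 0.0074 0.0470 0.0725
#> T_final = 0.05; phase acceptance: 0.05/0.01/0.01/0.01; converged: TRUE
```

The proliferation rate, differentiation rate and d₁ come back close to
the truth; γ and d₂ act on the small differentiated pool and are the
weakly identified directions at this design scale (see the methods
vignette).

A stochastic ensemble under the central model variant (constant rates,
lognormal field-to-field initial counts), started from the design-scale
per-field counts (9.9, 0.6, 0.3), reproduces the intermediate
mean–variance exponent:

```r
init <- unclass(ground_truth(p)$init) * 0.3   # expected counts per field
ens <- simulate_ensemble(p, init, n_runs = 3000, days = 0:7,
                         variant = 1, seed = 1)
fit_powerlaw(mean_var_series(ens$counts, 0:7, exclude_zeros = TRUE))
#> Taylor power law V = a M^b: a = 0.2449, b = 1.889 (R^2 = 0.9835, n = 22)
```

The slope b strictly between 1 (Poisson-like counts) and 2
(exponential/lognormal-like) is the signature the model is built to
explain: demographic branching noise plus initial-condition dispersal,
with no condition-to-condition rate variability needed.

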