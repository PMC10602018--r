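# surrosp

Covariate-adjusted measures of **surrogate paradox risk** for
individual-patient meta-analytic data.

## The problem

Clinical trials often rely on a surrogate endpoint S (tumor progression,
CD4 count, early blood pressure) in place of the true endpoint T of
interest. A surrogate can pass the usual validation criteria and still
mislead: the treatment improves the surrogate while harming the true
endpoint — the *surrogate paradox*. Because treatments can act differently
in different subpopulations, the risk of that paradox may also differ by
patient covariates, and a new trial enrolling a different population than
the historical trials may face more risk than the pooled analysis
suggests.

`surrosp` quantifies that risk in the meta-analytic causal-association
framework. Subject j in trial i contributes

```
S_ij = alpha_S + beta_S Z_ij + gamma_S X_ij + delta_S X_ij Z_ij
       + aS_i + bS_i Z_ij [+ cS_i X_ij + dS_i X_ij Z_ij] + eps_S,ij
```

(and likewise for T), with trial-level random effects ~ N(0, D) and
bivariate residuals ~ N(0, sigma). Two scenarios are supported: **S1**,
covariate effects constant across trials (4 random effects, any number of
covariates), and **S2**, covariate effects varying across trials (8 random
effects, one scalar or binary covariate). The trial-level treatment
effects at covariate level x,

```
Delta_S(x) = beta_S + delta_S x + bS_i [+ x dS_i]
Delta_T(x) = beta_T + delta_T x + bT_i [+ x dT_i]
```

are bivariate normal; under S1 the covariate shifts only the mean, under
S2 it also changes the covariance (`daa* = daa + x^2 d_ds,ds + 2x d_a,ds`,
etc.). From that law the package computes:

- **psi_SP13(x)** — probability the next trial's effects agree in sign
  (quadrants I or III of the (Delta_S, Delta_T) plane);
- **psi_SP123(x)** — probability of avoiding the *dangerous* paradox
  (quadrant IV: surrogate helped, outcome harmed);
- **psi_SP13N(x)** — the same for an *ongoing* trial, conditioning its
  random effects on partially collected data (true endpoint may be
  missing);
- **s(x)** — the smallest observed surrogate effect guaranteeing
  P(Delta_T < 0 | O_S = s, X = x) <= alpha;
- **R^2_trial** — the classical trial-level surrogacy measure.

Inference is fully Bayesian: a conjugate Gibbs sampler draws (mu, D,
sigma, random effects), every draw is transformed into the measures, and
equal-tailed credible intervals follow. A marginal WAIC (random effects
integrated out analytically) compares S1 against S2.

## Worked example

```r
library(surrosp)

params <- sp_sim_params("S2")          # reference generative parameters
paradox_measures(params, c(0, 1))
#>   x  psi_sp13 psi_sp123
#> 1 0 0.8451270 0.8546110
#> 2 1 0.7617019 0.9609251
```

At covariate level x = 0 there is a 84.5% chance that a new trial's
treatment effects on surrogate and outcome agree in sign; at x = 1 the
trial-varying covariate effects inflate the effect covariance and the
agreement probability drops to 76.2%, while the chance of avoiding the
dangerous quadrant rises to 96.1% (the mean effect on the true endpoint is
larger there).

```r
s_threshold(params, x = 1, alpha = 0.05, n1x = 25, n0x = 25)
#> s-threshold at x = 1, alpha = 0.05: s = 1.4757 (n1 = 25, n0 = 25)
```

An observed surrogate arm-difference of at least 1.48 among x = 1
subjects (25 per arm) caps the probability of a harmful true effect at 5%.

Estimation from data:

```r
design <- sp_design("S2", n_trials = 30, n_per_trial = 50)
dat <- simulate_meta(design, seed = 1)
fit <- gibbs_fit(dat, "S2", iterations = 2000, burn_in = 500, seed = 1)
posterior_measures(fit, x_levels = c(0, 1))
#>     measure x estimate lower upper n_failed
#> 1  psi_sp13 0    0.800 0.696 0.891        0
#> 2 psi_sp123 0    0.827 0.716 0.917        0
#> 3  psi_sp13 1    0.758 0.656 0.841        0
#> 4 psi_sp123 1    0.933 0.863 0.975        0
```

The 95% credible intervals cover the generating truths above. For an
ongoing trial with surrogate data but few or no true-endpoint
measurements, see `conditional_random_effects()` /
`posterior_partial_measures()`; for scenario choice, `marginal_waic()`;
for bias/coverage replication studies, `run_study()`. The methods
vignette (`vignettes/surrogate-paradox-risk.Rmd`) documents the model,
priors, and numerical choices.

## Command line

```sh
Rscript inst/cli/surrosp.R simulate --scenario S2 --n-trials 30 --n-per-trial 50 --seed 1 --out meta.tsv
Rscript inst/cli/surrosp.R fit --data meta.tsv --scenario S2 --out draws.tsv
Rscript inst/cli/surrosp.R compare --data meta.tsv
Rscript inst/cli/surrosp.R measures --params params.yaml --x-levels 0,1 --n1 25 --n0 25
Rscript inst/cli/surrosp.R partial --params params.yaml --data ongoing.tsv
Rscript inst/cli/surrosp.R svalue --params params.yaml --x 1 --alpha 0.05
```
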