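---
title: "Covariate-adjusted surrogate-paradox risk: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate-adjusted surrogate-paradox risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surrosp)
```

## The model

For surrogate $S_{ij}$ and true endpoint $T_{ij}$ of subject $j$ in trial
$i$, with randomized treatment $Z_{ij} \in \{0,1\}$ and covariate
$X_{ij}$, the package fits the bivariate linear mixed model

$$S_{ij} = \alpha_S + \beta_S Z_{ij} + \gamma_S X_{ij} + \delta_S X_{ij} Z_{ij}
 + a_{Si} + b_{Si} Z_{ij} \,[+\, c_{Si} X_{ij} + d_{Si} X_{ij} Z_{ij}] + \epsilon_{Sij},$$

and the analogous equation for $T_{ij}$. The residual pair is
$N_2(0, \sigma)$ and the trial-level random effects are
$N_q(0, D)$ with $q = 4$ (scenario **S1**: covariate effects constant
across trials; the bracketed terms absent) or $q = 8$ (scenario **S2**:
covariate effects vary by trial; one scalar or binary covariate). The
random-effect ordering is fixed throughout as
$(a_S, a_T, b_S, b_T[, c_S, c_T, d_S, d_T])$, and `write_params()` /
`read_params()` serialize $D$ under an unambiguous flat naming scheme
(`d_ss` … `d_dt_dt`) so that no flat-notation entry can be misread.

The trial-level causal treatment effects at covariate level $x$ are
$\Delta_S(x) = \beta_S + \delta_S x + b_{Si} (+ x\, d_{Si})$ and its $T$
analogue, jointly bivariate normal. Under S1 only the mean depends on
$x$; under S2 the covariance entries become

$$d_{aa}^*(x) = d_{aa} + x^2 d_{d_S d_S} + 2x\, d_{a d_S},\qquad
  d_{ab}^*(x) = d_{ab} + x\, d_{a d_T} + x\, d_{b d_S} + x^2 d_{d_S d_T},$$

and symmetrically for $d_{bb}^*$. The quadratic term is the *covariance*
$\mathrm{Cov}(d_{Si}, d_{Ti})$, a single entry of $D$ — not a product of
two entries; the implementation (`joint_effect_distribution()`) computes
all three entries as $E D E^\top$ for the $(1, x)$-pattern contrast $E$,
which keeps the result symmetric positive semidefinite by construction
whenever $D$ is. Covariates are used exactly as supplied (no centering or
scaling; binary covariates coded 0/1), $x$ may be any real number, and
parameter sets whose implied covariance is invalid are *rejected*, never
silently repaired — the only repair in the package is an eigenvalue clip
at $10^{-10}$ inside the Gibbs sampler, guarding against numerical jitter
in Wishart scale matrices.

## The risk measures

All four measures are functionals of the bivariate normal law of
$(\Delta_S(x), \Delta_T(x))$ (a beneficial effect is positive by
convention):

* $\Psi_{SP13}(x) = P(\Delta_S \Delta_T > 0) =
  1 - \Phi_1(0; m_S, v_{SS}) - \Phi_1(0; m_T, v_{TT}) + 2\Phi_2(\mathbf 0; m, V)$,
  the probability of sign agreement (quadrants I and III);
* $\Psi_{SP123}(x) = 1 - \Phi_1(0; m_T, v_{TT}) + \Phi_2(\mathbf 0; m, V)$,
  the probability of avoiding the dangerous quadrant IV;
* $\hat\Psi_{SP13N}(x)$, the same with the law conditioned on an ongoing
  trial's partial data (below);
* $s(x)$, the smallest observed surrogate arm-difference with
  $P(\Delta_T < 0 \mid O_S = s, X = x) \le \alpha$.

$\Psi_{SP123} \ge \Psi_{SP13}$ always, since quadrant IV is one of the two
quadrants $\Psi_{SP13}$ excludes. The bivariate normal CDF is evaluated
with `mvtnorm`'s deterministic TVPACK algorithm (absolute tolerance
$10^{-10}$, well inside the $10^{-7}$ accuracy the three-decimal
comparisons require); correlations within $10^{-12}$ of $\pm 1$ and
zero-variance margins are handled by exact degenerate formulas, and a
zero-variance margin with mean exactly zero is an error (the sign is
undefined). Results are clamped to $[0,1]$ only within $10^{-10}$.

For the $s$ threshold, the observed arm-difference $O_S(x)$ has variance
$\tilde d_{aa} = d_{aa}^* + \sigma_{ss}(1/n_{1x} + 1/n_{0x})$; the
conditional law of $\Delta_T$ given $O_S = s$ is normal, and the
implementation treats monotone numerical inversion of that conditional
probability as the source of truth, cross-checking the closed form

$$s^* = m_S - \frac{\tilde d_{aa}}{d_{ab}^*}\Big(\Phi^{-1}(\alpha)
  \sqrt{v_{TT} - (d_{ab}^*)^2/\tilde d_{aa}} + m_T\Big)$$

to $10^{-8}$. (The "$\Phi(\alpha;0,1)-1$" appearing in some statements of
the threshold is read as the standard-normal quantile
$\Phi^{-1}(\alpha)$; inverting the probability numerically insulates the
result against any sign or typo ambiguity in the closed form.) The
threshold requires $d_{ab}^* > 0$: with a nonpositive surrogate–outcome
effect association the direction of the inequality reverses and the
package raises an error rather than returning a misleading number. The
default $\alpha$ is 0.05; $n_{1x}, n_{0x}$ are planning values in a
prospective calculation and counted from data (via
`observed_surrogate_effect()`) retrospectively.

Marginal (covariate-averaged) risk uses the sample-average approximation
$\Psi = \int \Psi(x) P(x)\,dx \approx \sum_i w_i \Psi(x_i)$ with empirical
point masses at the observed covariate values (`marginal_psi()`).

## Conditional prediction for an ongoing trial

For a trial N with partially collected data — every subject has $S$, some
lack $T$ — the stacked observation vector and the trial's random effects
are jointly normal, so

$$\tilde\gamma_N = D W_N^\top V_N^{-1}(\Upsilon_N - M_N \mu), \qquad
  \tilde D_N = D - D W_N^\top V_N^{-1} W_N D, \qquad V_N = W_N D W_N^\top + R.$$

Because the joint is multivariate normal, *deleting* the rows belonging
to missing $T$ values is exactly analytic marginalization; the package
implements the deletion and unit-tests its equality (to $10^{-10}$) with
the dense stacked-matrix formula. Rather than forming the $2n \times 2n$
matrix $V_N$, the implementation applies the Woodbury identity over
per-subject $2\times 2$ (or, after deletion, $1\times 1$) residual
blocks: $\tilde\gamma_N = (I + DA)^{-1} D u$ and
$\tilde D_N = (I + DA)^{-1} D$ with $A = W^\top R^{-1} W$,
$u = W^\top R^{-1}(\Upsilon - M\mu)$ — $O(n)$ work and numerically
benign. A $10^{-8}$ floor on the residual variances guards the block
inverses; an exactly singular conditioning system raises an error rather
than being regularized further. With no data the prior $(0, D)$ is
returned, so the conditional measures reduce exactly to the unconditional
ones. $\tilde D_N \preceq D$ in the Loewner order on every call.

Under S2 the conditional law of $(\Delta_S(x), \Delta_T(x))$ combines the
predicted effects with weights $(1, x)$: mean
$\beta + \delta x + \tilde b + x \tilde d$ and covariance
$E \tilde D_N E^\top$ for the same contrast $E$ as in the unconditional
case. (Published statements of the S1 formula use the
$(\tilde d_{33}, \tilde d_{34}, \tilde d_{44})$ block directly, which the
contrast reproduces; the S2 combination is the natural extension implied
by the S2 effect definitions, reconstructed here since no explicit S2
display exists.) Parameters may be point estimates or, by default for
interval estimation, propagated per posterior draw
(`posterior_partial_measures()`).

## Bayesian estimation

Priors: $\mu \sim N(0, \Sigma_0)$ with $\Sigma_0 = 10^6 I$;
$\sigma^{-1} \sim W(\nu_\sigma, G)$ and $D^{-1} \sim W(\nu_D, F)$ in the
convention $E[W(\nu, S)] = \nu S$, with defaults
$W(q + 1, \tfrac{1}{q+2} I_q)$ for a $q$-dimensional precision — a point
worth stating prominently, because Wishart scale conventions differ
across software and the same prior is sometimes printed with the scale
inverted. The Gibbs sampler cycles the conjugate full conditionals in the
fixed order $D^{-1} \to \sigma^{-1} \to \{\gamma_i\} \to \mu$ (any fixed
order yields a valid kernel; one had to be chosen). In the
$\gamma_i$ update the cross-product uses the random-effect design $W$
(not the fixed-effect design $M$): the two coincide only when every fixed
effect has a random counterpart, as under S2.

Defaults are 4000 iterations, 1000 burn-in, thinning 1, one chain;
multiple chains split the generator stream deterministically
(`seed + 104729 (k-1)`) and `summary()` reports Gelman–Rubin
$\hat R$ when chains $\ge 2$. Initialization: $\mu$ from pooled least
squares, $D = I$, $\sigma = I$, $\gamma_i = 0$. Subjects missing $T$ are
excluded from the fit (they belong in the conditional-prediction path),
and single-arm trials are dropped with a warning, since they cannot
separate treatment effects from trial effects.

Each trial is collapsed onto sufficient statistics per unique design row
(counts, response sums, cross-products) — at most four groups per trial
with binary $Z$ and $X$ — so one sweep costs the same whether trials have
20 or 500 subjects, and trials sharing a count signature share one
Cholesky factorization in the $\gamma$ update. The full conditionals are
verified in the test suite against brute-force grid evaluation of the
joint posterior density, slice by slice, for all four blocks.

`posterior_measures()` transforms every retained draw into the measures
and reports posterior means with equal-tailed credible intervals; draws
violating the $s$-threshold precondition are counted and reported (with a
warning beyond 5%), never silently dropped. The `">0.99"` display
convention for near-certain probabilities is available through
`format_psi()` and `write_results()`.

Scenario choice uses the marginal WAIC: per draw, the random effects are
integrated out analytically, giving each trial a $2n_i$-dimensional
normal likelihood evaluated via the same Woodbury/determinant-lemma
identities (never forming $V_i$), and
$\mathrm{WAIC} = -2(\mathrm{lppd} - p_{\mathrm{WAIC}})$ with the
variance-based penalty. Marginal (rather than conditional) likelihoods
are the appropriate basis when the hypothesis under test is whether a
block of random effects has zero variance — a boundary hypothesis for
which likelihood-ratio asymptotics fail.

## The simulator and the replication study

`sp_sim_params()` encodes the reference generative settings:
$\alpha_S = \alpha_T = 1$, $\beta_S = 2$, $\beta_T = 1$,
$\gamma_S = \gamma_T = 0$, $\delta_S = -1$, $\delta_T = 1$; unit
random-effect variances with $d_{ab} = 0.5$ and all other base
off-diagonals 0.3; under S2, unit variances for the four covariate
random effects and 0.3 for every off-diagonal involving them (the
resulting $8\times 8$ matrix is verified positive definite at
construction). The residual covariance is not part of the published
settings (the true measures do not depend on it); the package uses
$\sigma_{ss} = \sigma_{tt} = 1$, $\sigma_{st} = 0.3$, matching the 0.3
used for the unspecified covariances. Half of each trial is treated;
the binary covariate is balanced within each arm when the arm size is
even, Bernoulli(0.5) otherwise.

Beyond normal errors, the simulator offers two stress families, both
location-0 and variance-matched to $\sigma$: a $t_{15}$ (heavier tails)
and a skew normal whose shape parameter is tied to its scale,
$\alpha = 0.1\,\omega$, with $\omega$ solved so the variance is one and
the location set so the mean is zero. That coupling is one reading of a
loosely specified convention ("shape equal to 0.1 times the location and
scale, centered at zero"); it is implemented in a single documented
helper so alternative readings are a one-line change. With
$\alpha \approx 0.1$ the implied skewness is mild (about $4\times10^{-4}$)
— the family perturbs the error *shape* without moving the first two
moments.

`run_study()` repeats simulate → fit → transform, comparing estimates
against analytic truths computed from the generating parameters (never
against published table entries: the published "true" $s$ rows are
internally inconsistent across trial counts, so $s$ truth is always
recomputed from the formula at stated $\alpha$ and arm counts, by default
$n/4$ per treatment-by-covariate cell). For $\hat\Psi_{SP13N}$ the final
trial is excluded from the fit and conditioned on its first half of
subjects, mirroring a trial midway through accrual. Replicate-level
failures are recorded and excluded with a reported count. An `"oracle"`
estimator that returns the truth exercises the bookkeeping (bias 0,
coverage 1) independently of the sampler.

The packaged test suite runs the study at reduced scale — 20 replicates
of the 100-trial × 20-subject design with 2000-iteration chains, and a
30-trial × 50-subject recovery fit at 4000 iterations — sizes chosen so
the whole suite completes in a few minutes while leaving the Monte-Carlo
bands (±0.05 on bias, ±10 points on coverage) wide enough to be
meaningful at 20 replicates.

## What the simulator does and does not emulate

The generator reproduces the study conditions the measures were designed
for: many trials of the same treatment/surrogate/endpoint combination,
balanced randomization, a single binary covariate, normal (or mildly
perturbed) errors, and exchangeable trial effects. Real meta-analytic
data typically violate several of these — unequal trial sizes, informative
missingness in $T$ (the simulator's missingness is by design, not
outcome-dependent), non-normal endpoints, and between-trial heterogeneity
in residual variance. Passing the packaged studies therefore demonstrates
internal consistency of estimator and generator under the stated model,
not robustness to those departures; the $t_{15}$ and skew-normal
families probe only the error-shape axis.

## Known limitations

* S2 supports exactly one covariate; more would enlarge $D$ quadratically
  and is rarely estimable with realistic trial counts.
* No ML/REML path: with $q = 8$ random effects the profiled likelihood
  frequently produces non-positive-definite $D$ estimates at realistic
  sample sizes, which is why estimation is Bayesian throughout.
* The $s$ threshold is reported per draw but is unstable when trials are
  few — wide, sign-crossing posteriors are expected and are reported
  honestly rather than truncated.
* Endpoints are Gaussian; binary or time-to-event endpoints would need a
  different joint model (e.g. copula-based) and are out of scope.
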