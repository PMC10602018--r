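# Data generation under the meta-analytic bivariate mixed model, and the
# replication study measuring bias / empirical SE / credible-interval
# coverage of the Bayesian measure estimates.

#' Generating parameters of the reference simulation settings
#'
#' The parameter sets used by the package's simulation study: fixed effects
#' alpha_S = alpha_T = 1, beta_S = 2, beta_T = 1, gamma_S = gamma_T = 0,
#' delta_S = -1, delta_T = 1; unit random-effect variances with
#' Cov(bS, bT) = 0.5 and all other base off-diagonals 0.3; under S2 the
#' four covariate random effects also have unit variance and every
#' off-diagonal entry involving them equals 0.3. The residual covariance is
#' sigma_ss = sigma_tt = 1, sigma_st = 0.3 (the true paradox measures do
#' not depend on sigma).
#'
#' @param scenario `"S1"` or `"S2"`.
#' @return an [sp_params] object.
#' @export
sp_sim_params <- function(scenario = c("S1", "S2")) {
  scenario <- match.arg(scenario)
  q <- if (scenario == "S2") 8L else 4L
  D <- matrix(0.3, q, q)
  diag(D) <- 1
  D[3, 4] <- D[4, 3] <- 0.5            # Cov(bS, bT)
  fixed <- c(alpha_S = 1, alpha_T = 1, beta_S = 2, beta_T = 1,
             gamma_S = 0, gamma_T = 0, delta_S = -1, delta_T = 1)
  sigma <- matrix(c(1, 0.3, 0.3, 1), 2)
  sp_params(scenario, fixed, D, sigma)
}

# Standardized (mean 0, variance 1) error generators.
.rerr_std <- function(family, n) {
  switch(family,
    normal = stats::rnorm(n),
    t15 = stats::rt(n, df = 15) * sqrt(13 / 15),
    skew_normal = .rskewnorm_std(n),
    stop("unknown error family '", family, "'", call. = FALSE))
}

# Standardized skew normal whose shape parameter is tied to its scale,
# alpha = 0.1 * omega, with omega solved so the variance is 1 and the
# location chosen so the mean is 0 (stochastic representation
# X = xi + omega * (delta |Z0| + sqrt(1 - delta^2) Z1)).
.skewnorm_std_pars <- function(shape_per_scale = 0.1) {
  f <- function(omega) {
    a <- shape_per_scale * omega
    d <- a / sqrt(1 + a^2)
    omega^2 * (1 - 2 * d^2 / pi) - 1
  }
  omega <- stats::uniroot(f, c(1, 2), tol = 1e-12)$root
  alpha <- shape_per_scale * omega
  delta <- alpha / sqrt(1 + alpha^2)
  list(omega = omega, alpha = alpha, delta = delta,
       xi = -omega * delta * sqrt(2 / pi))
}

.rskewnorm_std <- function(n, shape_per_scale = 0.1) {
  p <- .skewnorm_std_pars(shape_per_scale)
  z0 <- abs(stats::rnorm(n)); z1 <- stats::rnorm(n)
  p$xi + p$omega * (p$delta * z0 + sqrt(1 - p$delta^2) * z1)
}

#' Simulation design
#'
#' @param scenario `"S1"` or `"S2"`.
#' @param n_trials number of trials (reference settings: 30 or 100).
#' @param n_per_trial subjects per trial (reference settings: 20, 50, 500).
#'   Half of each trial is assigned to treatment; the binary covariate is
#'   balanced across treatment-by-covariate cells when the size allows.
#' @param n_replicates replicates for [run_study()] (reference: 200).
#' @param error_family `"normal"`, `"t15"` or `"skew_normal"`; non-normal
#'   families are location-0, variance-matched to `sigma`.
#' @param params generating [sp_params]; defaults to [sp_sim_params()].
#' @return object of class `sp_design`.
#' @export
sp_design <- function(scenario = c("S1", "S2"), n_trials = 30,
                      n_per_trial = 50, n_replicates = 200,
                      error_family = c("normal", "t15", "skew_normal"),
                      params = sp_sim_params(scenario)) {
  scenario <- match.arg(scenario)
  error_family <- match.arg(error_family)
  stopifnot(inherits(params, "sp_params"), params$scenario == scenario,
            n_trials >= 1, n_per_trial >= 2, n_replicates >= 1)
  .check_psd(params$D, "D")   # re-verified after any user edit of defaults
  structure(list(scenario = scenario, n_trials = as.integer(n_trials),
                 n_per_trial = as.integer(n_per_trial),
                 n_replicates = as.integer(n_replicates),
                 error_family = error_family, params = params),
            class = "sp_design")
}

# Balanced treatment and covariate assignment within a trial: half treated;
# within each arm half x=1 when divisible, else Bernoulli(0.5).
.assign_zx <- function(n) {
  z <- sample(rep(c(0L, 1L), length.out = n))
  x <- integer(n)
  for (arm in c(0L, 1L)) {
    idx <- which(z == arm); m <- length(idx)
    x[idx] <- if (m %% 2 == 0) sample(rep(c(0L, 1L), m / 2))
              else stats::rbinom(m, 1, 0.5)
  }
  list(z = z, x = x)
}

#' Simulate a meta-analytic dataset
#'
#' Draws trial-level random effects from N(0, D), subject-level errors from
#' the chosen bivariate family (variance-matched to `sigma`), and assembles
#' surrogate and true endpoint by the model equations. Treatment is
#' balanced within trial and the binary covariate is balanced within each
#' arm.
#'
#' @param design an [sp_design].
#' @param seed integer seed; required for reproducibility when given.
#' @return data frame with columns `trial`, `subject`, `z`, `x`, `s`, `t`,
#'   with the generating random effects in attribute `"random_effects"`
#'   (one row per trial) and the design in attribute `"design"`.
#' @export
simulate_meta <- function(design, seed = NULL) {
  stopifnot(inherits(design, "sp_design"))
  if (!is.null(seed)) set.seed(seed)
  pr <- design$params
  N <- design$n_trials; n <- design$n_per_trial
  q <- if (pr$scenario == "S2") 8L else 4L
  G <- mvtnorm::rmvnorm(N, sigma = pr$D)
  colnames(G) <- .re_labels(pr$scenario)
  ch <- chol(pr$sigma)
  fx <- pr$fixed
  gS <- if (pr$p >= 1) fx["gamma_S"] else 0
  gT <- if (pr$p >= 1) fx["gamma_T"] else 0
  dS <- if (pr$p >= 1) fx["delta_S"] else 0
  dT <- if (pr$p >= 1) fx["delta_T"] else 0
  out <- vector("list", N)
  for (i in seq_len(N)) {
    zx <- .assign_zx(n)
    z <- zx$z; x <- zx$x
    e <- cbind(.rerr_std(design$error_family, n),
               .rerr_std(design$error_family, n)) %*% ch
    g <- G[i, ]
    s <- fx["alpha_S"] + fx["beta_S"] * z + gS * x + dS * x * z +
      g["aS"] + g["bS"] * z + e[, 1]
    t <- fx["alpha_T"] + fx["beta_T"] * z + gT * x + dT * x * z +
      g["aT"] + g["bT"] * z + e[, 2]
    if (pr$scenario == "S2") {
      s <- s + g["cS"] * x + g["dS"] * x * z
      t <- t + g["cT"] * x + g["dT"] * x * z
    }
    out[[i]] <- data.frame(trial = i, subject = seq_len(n), z = z, x = x,
                           s = as.numeric(s), t = as.numeric(t))
  }
  dat <- do.call(rbind, out)
  attr(dat, "random_effects") <- G
  attr(dat, "design") <- design
  dat
}

# Analytic truth for the studied quantities at one covariate level.
.study_truth <- function(params, x, alpha, n1x, n0x) {
  j <- joint_effect_distribution(params, x)
  c(psi_sp13 = psi_sp13(j), psi_sp123 = psi_sp123(j),
    psi_sp13N = psi_sp13(j),
    s = tryCatch(s_threshold(params, x, alpha, n1x, n0x)$s_closed_form,
                 error = function(e) NA_real_))
}

#' Replication study of estimator bias, SE and coverage
#'
#' Repeatedly simulates a meta-analytic dataset under `design`, estimates
#' the paradox-risk measures (by the Gibbs sampler, or by an oracle that
#' returns the truth — useful for validating the bookkeeping), and tabulates
#' bias, empirical SE and 95% credible-interval coverage against the
#' analytic true values computed from the generating parameters. For the
#' conditional measure `psi_sp13N` the final trial is held out of the fit
#' and conditioned on its first half of subjects.
#'
#' @param design an [sp_design]; `design$n_replicates` replicates are run.
#' @param x_levels covariate levels to evaluate.
#' @param quantities subset of `c("psi_sp13", "psi_sp123", "psi_sp13N", "s")`.
#' @param estimator `"bayes"` or `"oracle"`.
#' @param mcmc list of [gibbs_fit()] settings
#'   (`iterations`, `burn_in`, `thinning`).
#' @param alpha risk level for the s-threshold.
#' @param n1x,n0x per-arm counts for the s-threshold truth and estimates;
#'   default `n_per_trial / 4` (equal treatment-by-covariate cells).
#' @param level credible level for coverage.
#' @param seed integer seed; replicate r uses `seed + r`.
#' @return data frame with one row per quantity and level: `quantity`, `x`,
#'   `true_value`, `bias`, `emp_se`, `coverage`, `n_fail`, `n_replicates`.
#' @export
run_study <- function(design, x_levels = c(0, 1),
                      quantities = c("psi_sp13", "psi_sp123"),
                      estimator = c("bayes", "oracle"),
                      mcmc = list(iterations = 2000, burn_in = 500, thinning = 1),
                      alpha = 0.05, n1x = NULL, n0x = NULL,
                      level = 0.95, seed = 1L) {
  stopifnot(inherits(design, "sp_design"), design$n_replicates >= 2)
  estimator <- match.arg(estimator)
  quantities <- match.arg(quantities,
                          c("psi_sp13", "psi_sp123", "psi_sp13N", "s"),
                          several.ok = TRUE)
  if (is.null(n1x)) n1x <- max(1L, design$n_per_trial %/% 4L)
  if (is.null(n0x)) n0x <- max(1L, design$n_per_trial %/% 4L)
  pr <- design$params
  truth <- vapply(x_levels, function(x)
    .study_truth(pr, x, alpha, n1x, n0x), numeric(4))
  colnames(truth) <- as.character(x_levels)

  R <- design$n_replicates
  est <- lo <- hi <- array(NA_real_,
    dim = c(R, length(quantities), length(x_levels)),
    dimnames = list(NULL, quantities, as.character(x_levels)))
  n_fail <- 0L
  for (r in seq_len(R)) {
    res <- tryCatch(
      .study_replicate(design, x_levels, quantities, estimator, mcmc,
                       alpha, n1x, n0x, level, seed + r),
      error = function(e) e)
    if (inherits(res, "error")) { n_fail <- n_fail + 1L; next }
    est[r, , ] <- res$est; lo[r, , ] <- res$lo; hi[r, , ] <- res$hi
  }
  rows <- list()
  for (qt in quantities) for (xi in as.character(x_levels)) {
    tv <- truth[qt, xi]
    e <- est[, qt, xi]; ok <- !is.na(e)
    rows[[length(rows) + 1]] <- data.frame(
      quantity = qt, x = as.numeric(xi), true_value = tv,
      bias = mean(e[ok] - tv), emp_se = stats::sd(e[ok]),
      coverage = mean(lo[ok, qt, xi] <= tv & tv <= hi[ok, qt, xi]),
      n_fail = sum(!ok), n_replicates = R)
  }
  out <- do.call(rbind, rows)
  attr(out, "n_replicate_failures") <- n_fail
  out
}

.study_replicate <- function(design, x_levels, quantities, estimator, mcmc,
                             alpha, n1x, n0x, level, seed) {
  nq <- length(quantities); nx <- length(x_levels)
  est <- lo <- hi <- matrix(NA_real_, nq, nx,
                            dimnames = list(quantities, as.character(x_levels)))
  if (estimator == "oracle") {
    for (k in seq_len(nx)) {
      tv <- .study_truth(design$params, x_levels[k], alpha, n1x, n0x)
      est[, k] <- lo[, k] <- hi[, k] <- tv[quantities]
    }
    return(list(est = est, lo = lo, hi = hi))
  }
  dat <- simulate_meta(design, seed = seed)
  need_partial <- "psi_sp13N" %in% quantities
  fit_dat <- dat
  if (need_partial) {
    last <- design$n_trials
    fit_dat <- dat[dat$trial != last, , drop = FALSE]
    part <- dat[dat$trial == last &
                  dat$subject <= design$n_per_trial %/% 2L, , drop = FALSE]
  }
  fit <- gibbs_fit(fit_dat, scenario = design$scenario,
                   iterations = mcmc$iterations, burn_in = mcmc$burn_in,
                   thinning = if (is.null(mcmc$thinning)) 1 else mcmc$thinning,
                   seed = seed)
  do_s <- "s" %in% quantities
  pm <- posterior_measures(fit, x_levels = x_levels, alpha = alpha,
                           n1x = if (do_s) n1x, n0x = if (do_s) n0x,
                           level = level)
  for (qt in intersect(quantities, c("psi_sp13", "psi_sp123", "s"))) {
    for (k in seq_len(nx)) {
      row <- pm[pm$measure == qt & pm$x == x_levels[k], ]
      est[qt, k] <- row$estimate; lo[qt, k] <- row$lower; hi[qt, k] <- row$upper
    }
  }
  if (need_partial) {
    pd <- .posterior_partial(fit, part, x_levels, level)
    est["psi_sp13N", ] <- pd$estimate
    lo["psi_sp13N", ] <- pd$lower; hi["psi_sp13N", ] <- pd$upper
  }
  list(est = est, lo = lo, hi = hi)
}
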