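# Conjugate Gibbs sampler: full-conditional correctness against brute-force
# density evaluation, determinism, contraction, and the posterior measure
# transformation.

# tiny fixed dataset: 2 trials x 4 subjects, one covariate
tiny_data <- function() {
  set.seed(101)
  data.frame(trial = rep(1:2, each = 4), subject = rep(1:4, 2),
             z = rep(c(1, 0), 4), x = rep(c(0, 1), each = 2, times = 2),
             s = rnorm(8, 1), t = rnorm(8, 1))
}

# brute-force log joint posterior (up to a constant) as a function of the
# parameters, evaluated subject by subject with dmvnorm -- independent of
# the sampler's sufficient-statistic algebra
brute_log_joint <- function(data, scenario, mu, D, sigma, Gamma, prior) {
  p <- if ("x" %in% names(data)) 1L else 0L
  ll <- 0
  trials <- sort(unique(data$trial))
  for (r in seq_len(nrow(data))) {
    i <- match(data$trial[r], trials)
    M <- surrosp:::.m_rows(p, data$z[r], data$x[r])
    W <- surrosp:::.w_rows(scenario, data$z[r], data$x[r])
    m <- drop(M %*% mu + W %*% Gamma[i, ])
    ll <- ll + mvtnorm::dmvnorm(c(data$s[r], data$t[r]), m, sigma, log = TRUE)
  }
  for (i in seq_along(trials))
    ll <- ll + mvtnorm::dmvnorm(Gamma[i, ], sigma = D, log = TRUE)
  ll <- ll + mvtnorm::dmvnorm(mu, sigma = prior$Sigma0, log = TRUE)
  q <- nrow(D)
  ll + ldwish(solve(sigma), prior$v_sigma, prior$G) +
    ldwish(solve(D), prior$v_D, prior$F_D)
}

# Wishart log density (up to an additive constant) for W(v, S)
ldwish <- function(Q, v, S) {
  q <- nrow(Q)
  (v - q - 1) / 2 * determinant(Q, logarithm = TRUE)$modulus[1] -
    sum(solve(S) * Q) / 2
}

test_that("full conditionals match brute-force slices of the joint posterior", {
  dat <- tiny_data()
  scen <- "S1"; q <- 4L; pf <- 8L
  prior <- sp_prior(q, pf, Sigma0 = diag(4, pf))
  set.seed(5)
  mu <- rnorm(pf, 0, .5)
  D <- diag(q) + 0.2; sigma <- matrix(c(1, .2, .2, 1), 2)
  Gamma <- matrix(rnorm(2 * q, 0, .5), 2, q)
  ss <- surrosp:::.suffstats(dat, scen, 1L)

  norm_slice <- function(lp) {
    d <- exp(lp - max(lp)); d / sum(d)
  }

  # --- mu conditional: grid over the beta_S component
  sig_inv <- solve(sigma)
  S3_inv <- solve(prior$Sigma0)
  rhs <- numeric(pf)
  for (c in seq_len(ss$C)) {
    Msig <- crossprod(ss$M[[c]], sig_inv)
    S3_inv <- S3_inv + sum(ss$ncount[, c]) * (Msig %*% ss$M[[c]])
    gs <- colSums(ss$ncount[, c] * Gamma)
    SY <- c(sum(ss$sumS[, c]), sum(ss$sumT[, c]))
    rhs <- rhs + drop(Msig %*% (SY - ss$W[[c]] %*% gs))
  }
  S3 <- solve(S3_inv)
  mu_mean <- drop(S3 %*% rhs)
  grid <- seq(mu_mean[3] - 2, mu_mean[3] + 2, length.out = 61)
  lp_brute <- vapply(grid, function(g) {
    mu2 <- mu; mu2[3] <- g
    brute_log_joint(dat, scen, mu2, D, sigma, Gamma, prior)
  }, 0)
  # analytic conditional of mu[3] given the others within N(mu_mean, S3)
  others <- (1:pf)[-3]
  cm <- mu_mean[3] + drop(S3[3, others] %*%
                            solve(S3[others, others], mu[others] - mu_mean[others]))
  cv <- S3[3, 3] - drop(S3[3, others] %*% solve(S3[others, others], S3[others, 3]))
  lp_analytic <- dnorm(grid, cm, sqrt(cv), log = TRUE)
  expect_equal(norm_slice(lp_brute), norm_slice(lp_analytic), tolerance = 1e-6)

  # --- gamma_1 conditional: grid over its bS component
  K <- Reduce(`+`, lapply(seq_len(ss$C), function(c)
    ss$ncount[1, c] * crossprod(ss$W[[c]], sig_inv %*% ss$W[[c]])))
  u <- Reduce(`+`, lapply(seq_len(ss$C), function(c) {
    sy <- c(ss$sumS[1, c], ss$sumT[1, c])
    drop(crossprod(ss$W[[c]], sig_inv) %*% (sy - ss$ncount[1, c] * ss$M[[c]] %*% mu))
  }))
  S2 <- solve(K + solve(D))
  g_mean <- drop(S2 %*% u)
  grid_g <- seq(g_mean[3] - 2, g_mean[3] + 2, length.out = 61)
  lp_brute_g <- vapply(grid_g, function(g) {
    G2 <- Gamma; G2[1, 3] <- g
    brute_log_joint(dat, scen, mu, D, sigma, G2, prior)
  }, 0)
  oth <- c(1, 2, 4)
  cmg <- g_mean[3] + drop(S2[3, oth] %*%
                            solve(S2[oth, oth], Gamma[1, oth] - g_mean[oth]))
  cvg <- S2[3, 3] - drop(S2[3, oth] %*% solve(S2[oth, oth], S2[oth, 3]))
  expect_equal(norm_slice(lp_brute_g),
               norm_slice(dnorm(grid_g, cmg, sqrt(cvg), log = TRUE)),
               tolerance = 1e-6)

  # --- D^-1 conditional: grid over a diagonal element of the precision
  scale_D <- solve(crossprod(Gamma) + solve(prior$F_D))
  df_D <- 2 + prior$v_D
  Q0 <- solve(D)
  grid_q <- seq(0.4, 3, length.out = 41)
  lp_brute_D <- vapply(grid_q, function(g) {
    Q <- Q0; Q[1, 1] <- g
    # brute_log_joint's prior term is already a density in Q = D^-1, so the
    # slice is the posterior density of Q with no Jacobian needed
    brute_log_joint(dat, scen, mu, solve(Q), sigma, Gamma, prior)
  }, 0)
  lp_analytic_D <- vapply(grid_q, function(g) {
    Q <- Q0; Q[1, 1] <- g
    ldwish(Q, df_D, scale_D)
  }, 0)
  expect_equal(norm_slice(lp_brute_D), norm_slice(lp_analytic_D),
               tolerance = 1e-6)

  # --- sigma^-1 conditional likewise
  T1 <- matrix(0, 2, 2); T2 <- matrix(0, 2, 2)
  for (c in seq_len(ss$C)) {
    m0 <- drop(ss$M[[c]] %*% mu); Wc <- ss$W[[c]]
    SY <- c(sum(ss$sumS[, c]), sum(ss$sumT[, c]))
    SYg <- crossprod(cbind(ss$sumS[, c], ss$sumT[, c]), Gamma)
    gs <- colSums(ss$ncount[, c] * Gamma)
    Qc <- crossprod(Gamma * ss$ncount[, c], Gamma)
    nt <- sum(ss$ncount[, c])
    T1 <- T1 + tcrossprod(SY, m0) + SYg %*% t(Wc)
    Wg <- drop(Wc %*% gs)
    T2 <- T2 + nt * tcrossprod(m0) + tcrossprod(m0, Wg) +
      tcrossprod(Wg, m0) + Wc %*% Qc %*% t(Wc)
  }
  S1m <- ss$YYtot - T1 - t(T1) + T2
  scale_s <- solve(S1m + solve(prior$G))
  df_s <- ss$n_total + prior$v_sigma
  P0 <- solve(sigma)
  grid_p <- seq(0.3, 2.5, length.out = 41)
  lp_brute_s <- vapply(grid_p, function(g) {
    P <- P0; P[1, 1] <- g
    brute_log_joint(dat, scen, mu, D, solve(P), Gamma, prior)
  }, 0)
  lp_analytic_s <- vapply(grid_p, function(g) {
    P <- P0; P[1, 1] <- g
    ldwish(P, df_s, scale_s)
  }, 0)
  expect_equal(norm_slice(lp_brute_s), norm_slice(lp_analytic_s),
               tolerance = 1e-6)
})

test_that("fits are bitwise-reproducible given a seed", {
  dat <- tiny_data()
  f1 <- gibbs_fit(dat, "S1", iterations = 60, burn_in = 20, seed = 9)
  f2 <- gibbs_fit(dat, "S1", iterations = 60, burn_in = 20, seed = 9)
  expect_identical(f1$mu, f2$mu)
  expect_identical(f1$D, f2$D)
  expect_identical(f1$sigma, f2$sigma)
  f3 <- gibbs_fit(dat, "S1", iterations = 60, burn_in = 20, seed = 10)
  expect_false(identical(f1$mu, f3$mu))
})

test_that("a near-empty dataset yields wide, not falsely precise, posteriors", {
  dat <- data.frame(trial = 1, subject = 1:4, z = c(1, 1, 0, 0),
                    s = rnorm(4), t = rnorm(4))
  fit <- gibbs_fit(dat, "S1", iterations = 600, burn_in = 100, seed = 2)
  expect_gt(sd(fit$mu[, "alpha_S"]), 1)
})

test_that("single-arm trials are dropped and missing T excluded with warnings", {
  dat <- rbind(tiny_data(),
               data.frame(trial = 3, subject = 1:2, z = c(1, 1),
                          x = c(0, 1), s = rnorm(2), t = rnorm(2)))
  dat$t[1] <- NA
  expect_warning(expect_warning(
    gibbs_fit(dat, "S1", iterations = 40, burn_in = 10, seed = 1),
    "missing T"), "single-arm")
})

test_that("posterior uncertainty of beta_S contracts as trials grow", {
  sds <- vapply(c(10, 40), function(N) {
    d <- sp_design("S1", n_trials = N, n_per_trial = 20, n_replicates = 2)
    dat <- simulate_meta(d, seed = 100 + N)
    fit <- gibbs_fit(dat, "S1", iterations = 800, burn_in = 300, seed = 1)
    sd(fit$mu[, "beta_S"])
  }, 0)
  expect_lt(sds[2], sds[1])
})

test_that("posterior measures summarize draws with credible intervals", {
  d <- sp_design("S1", n_trials = 15, n_per_trial = 20, n_replicates = 2)
  dat <- simulate_meta(d, seed = 8)
  fit <- gibbs_fit(dat, "S1", iterations = 500, burn_in = 200, seed = 4)
  # a wide posterior may make the s-threshold undefined for some draws;
  # that reporting is tested separately below
  pm <- suppressWarnings(posterior_measures(fit, x_levels = c(0, 1),
                                            n1x = 5, n0x = 5))
  expect_setequal(unique(pm$measure), c("psi_sp13", "psi_sp123", "s"))
  psi <- pm[pm$measure != "s", ]
  expect_true(all(psi$lower <= psi$estimate & psi$estimate <= psi$upper))
  expect_true(all(psi$lower >= 0 & psi$upper <= 1))
  # psi_sp123 >= psi_sp13 draw by draw implies it for the posterior means
  for (x in c(0, 1))
    expect_gte(pm$estimate[pm$measure == "psi_sp123" & pm$x == x],
               pm$estimate[pm$measure == "psi_sp13" & pm$x == x])
})

test_that("degenerate identical draws give zero-width intervals; failures are counted", {
  q <- 4L; R <- 120L
  mu <- matrix(rep(c(1, 1, 2, 1, 0, 0, -1, 1), each = R), R, 8)
  colnames(mu) <- fixed_effect_names(1)
  D <- array(rep(diag(q) + 0.2, R), c(q, q, R))
  sg <- array(rep(diag(2), R), c(2, 2, R))
  fake <- structure(list(mu = mu, D = D, sigma = sg,
                         chain = rep(1L, R), scenario = "S1", p = 1L,
                         seed = 1L),
                    class = "sp_draws")
  pm <- posterior_measures(fake, x_levels = 0, n1x = 10, n0x = 10)
  expect_equal(pm$lower, pm$upper)
  expect_equal(pm$n_failed, rep(0L, nrow(pm)))
  # negative surrogate-outcome covariance: the s-threshold is undefined
  D2 <- D; D2[3, 4, ] <- D2[4, 3, ] <- -0.5
  fake2 <- fake; fake2$D <- D2
  expect_warning(pm2 <- posterior_measures(fake2, x_levels = 0,
                                           n1x = 10, n0x = 10),
                 "undefined")
  expect_equal(pm2$n_failed[pm2$measure == "s"], R)
  expect_true(is.nan(pm2$estimate[pm2$measure == "s"]))
  expect_error(posterior_measures(fake[["mu"]][1:50, ], 0), "sp_draws")
})

test_that("prior draws transform to a measure distribution consistent with prior predictive", {
  set.seed(77)
  R <- 400L
  mu <- cbind(rnorm(R, 2, .3), rnorm(R, 1, .3), rnorm(R, 2, .3), rnorm(R, 1, .3))
  # treat columns as (aS..)-free p = 0 layout: mu = (alpha_S, alpha_T, beta_S, beta_T)
  colnames(mu) <- fixed_effect_names(0)
  D <- array(0, c(4, 4, R)); sg <- array(rep(diag(2), R), c(2, 2, R))
  for (r in seq_len(R)) {
    W <- stats::rWishart(1, 6, diag(0.1, 4))[, , 1]
    D[, , r] <- solve(W)
  }
  fake <- structure(list(mu = mu, D = D, sigma = sg, chain = rep(1L, R),
                         scenario = "S1", p = 0L, seed = 1L),
                    class = "sp_draws")
  pm <- posterior_measures(fake, x_levels = numeric(1))
  # prior-predictive Monte Carlo: draw one effect pair per prior draw
  agree <- vapply(seq_len(R), function(r) {
    ef <- drop(mvtnorm::rmvnorm(1, mu[r, 3:4], D[3:4, 3:4, r]))
    as.numeric(ef[1] * ef[2] > 0)
  }, 0)
  mc <- mean(agree)
  est <- pm$estimate[pm$measure == "psi_sp13"]
  expect_lt(abs(est - mc), 4 * sqrt(mc * (1 - mc) / R))
})
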