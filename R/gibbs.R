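# Fully Bayesian estimation of the bivariate mixed model by a conjugate
# Gibbs sampler, transformation of draws into posterior distributions of
# the paradox-risk measures, and marginal-WAIC scenario comparison.
#
# The per-iteration cost is kept independent of the number of subjects by
# collapsing each trial onto sufficient statistics per unique design row
# (z, x): counts, surrogate/endpoint sums and total cross-products. With a
# binary treatment and binary covariate there are at most four such groups
# per trial.

#' Prior specification for the Gibbs sampler
#'
#' Conjugate priors: mu ~ N(0, Sigma0); sigma^-1 ~ W(v_sigma, G);
#' D^-1 ~ W(v_D, F). The Wishart convention is W(v, S) with expectation
#' v S for the precision matrix. Defaults follow the reference analysis:
#' Sigma0 = 10^6 I, and W(q + 1, (1/(q+2)) I_q) for a q-dimensional
#' precision (q = 2 for sigma, 4 or 8 for D).
#'
#' @param q dimension of the random-effect vector (4 for S1, 8 for S2).
#' @param p_fixed dimension of the fixed-effect vector.
#' @param Sigma0 prior covariance of mu.
#' @param v_sigma,G Wishart degrees of freedom and scale for sigma^-1.
#' @param v_D,F_D Wishart degrees of freedom and scale for D^-1.
#' @return object of class `sp_prior`.
#' @export
sp_prior <- function(q, p_fixed,
                     Sigma0 = diag(1e6, p_fixed),
                     v_sigma = 3, G = diag(1 / 4, 2),
                     v_D = q + 1, F_D = diag(1 / (q + 2), q)) {
  stopifnot(v_sigma >= 2, v_D >= q)
  .check_psd(Sigma0, "Sigma0"); .check_psd(G, "G"); .check_psd(F_D, "F_D")
  structure(list(q = q, p_fixed = p_fixed, Sigma0 = Sigma0,
                 v_sigma = v_sigma, G = G, v_D = v_D, F_D = F_D),
            class = "sp_prior")
}

# Collapse a validated dataset onto per-trial, per-design-row sufficient
# statistics. Returns combo design matrices and N x C count/sum arrays.
.suffstats <- function(data, scenario, p) {
  xcols <- if (p > 0) {
    if (p == 1 && "x" %in% names(data)) "x" else paste0("x", seq_len(p))
  } else character(0)
  key <- do.call(paste, c(list(data$z), data[xcols], list(sep = "\r")))
  combos <- !duplicated(key)
  ckey <- key[combos]
  C <- length(ckey)
  cz <- data$z[combos]
  cx <- if (p > 0) as.matrix(data[combos, xcols, drop = FALSE]) else
    matrix(0, C, 0)
  M <- lapply(seq_len(C), function(c) .m_rows(p, cz[c], cx[c, ]))
  W <- lapply(seq_len(C), function(c) .w_rows(scenario, cz[c], cx[c, ]))
  ci <- match(key, ckey)
  trials <- sort(unique(data$trial))
  ti <- match(data$trial, trials)
  N <- length(trials)
  ncount <- matrix(0, N, C)
  sumS <- matrix(0, N, C); sumT <- matrix(0, N, C)
  for (r in seq_len(nrow(data))) {
    i <- ti[r]; c <- ci[r]
    ncount[i, c] <- ncount[i, c] + 1
    sumS[i, c] <- sumS[i, c] + data$s[r]
    sumT[i, c] <- sumT[i, c] + data$t[r]
  }
  Y <- cbind(data$s, data$t)
  YYtot <- crossprod(Y)
  YYtrial <- array(0, c(2, 2, N))
  for (i in seq_len(N)) {
    Yi <- Y[ti == i, , drop = FALSE]
    YYtrial[, , i] <- crossprod(Yi)
  }
  list(trials = trials, N = N, C = C, M = M, W = W,
       ncount = ncount, sumS = sumS, sumT = sumT,
       YYtot = YYtot, YYtrial = YYtrial, n_i = rowSums(ncount),
       n_total = nrow(data))
}

.clip_pd <- function(m, tol = 1e-10) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (min(e$values) < tol) {
    warning("non-PD scale matrix in a Wishart update; eigenvalues clipped at ",
            tol, call. = FALSE)
    e$values <- pmax(e$values, tol)
  }
  e$vectors %*% (e$values * t(e$vectors))
}

# One chain of the Gibbs sampler over combo sufficient statistics.
.gibbs_chain <- function(ss, prior, iterations, burn_in, thinning,
                         store_gamma, seed) {
  set.seed(seed)
  q <- prior$q; pf <- prior$p_fixed
  N <- ss$N; C <- ss$C
  Sigma0_inv <- solve(prior$Sigma0)
  G_inv <- solve(prior$G)
  F_inv <- solve(prior$F_D)

  # initialization: mu by pooled least squares, D and sigma identity,
  # random effects zero
  MtM <- Reduce(`+`, lapply(seq_len(C), function(c)
    sum(ss$ncount[, c]) * crossprod(ss$M[[c]])))
  Mty <- Reduce(`+`, lapply(seq_len(C), function(c)
    crossprod(ss$M[[c]], c(sum(ss$sumS[, c]), sum(ss$sumT[, c])))))
  mu <- drop(solve(MtM + diag(1e-8, pf), Mty))
  D <- diag(q); D_inv <- diag(q)
  sigma <- diag(2)
  Gamma <- matrix(0, N, q)

  # group trials sharing a count signature: they share the gamma-update
  # precision and can be drawn in one vectorized step
  sig_key <- apply(ss$ncount, 1, paste, collapse = ",")
  groups <- split(seq_len(N), sig_key)

  n_keep <- length(seq(burn_in + 1L, iterations, by = thinning))
  mu_out <- matrix(NA_real_, n_keep, pf)
  D_out <- array(NA_real_, c(q, q, n_keep))
  sigma_out <- array(NA_real_, c(2, 2, n_keep))
  gamma_out <- if (store_gamma) array(NA_real_, c(N, q, n_keep)) else NULL
  keep_at <- seq(burn_in + 1L, iterations, by = thinning)
  k <- 0L

  for (it in seq_len(iterations)) {
    # --- D^-1 | . ~ W(N + v_D, (sum gamma gamma' + F^-1)^-1)
    scale_D <- .clip_pd(solve(crossprod(Gamma) + F_inv))
    D_inv <- stats::rWishart(1, N + prior$v_D, scale_D)[, , 1]
    D <- chol2inv(chol(D_inv))

    # --- sigma^-1 | . ~ W(sum n_i + v_sigma, (S1 + G^-1)^-1)
    T1 <- matrix(0, 2, 2); T2 <- matrix(0, 2, 2)
    for (c in seq_len(C)) {
      m0 <- drop(ss$M[[c]] %*% mu)
      Wc <- ss$W[[c]]
      SY <- c(sum(ss$sumS[, c]), sum(ss$sumT[, c]))
      SYg <- crossprod(cbind(ss$sumS[, c], ss$sumT[, c]), Gamma)  # 2 x q
      gs <- colSums(ss$ncount[, c] * Gamma)
      Qc <- crossprod(Gamma * ss$ncount[, c], Gamma)
      nt <- sum(ss$ncount[, c])
      T1 <- T1 + tcrossprod(SY, m0) + SYg %*% t(Wc)
      Wg <- drop(Wc %*% gs)
      T2 <- T2 + nt * tcrossprod(m0) + tcrossprod(m0, Wg) +
        tcrossprod(Wg, m0) + Wc %*% Qc %*% t(Wc)
    }
    S1 <- ss$YYtot - T1 - t(T1) + T2
    scale_sig <- .clip_pd(solve(S1 + G_inv))
    sig_inv <- stats::rWishart(1, ss$n_total + prior$v_sigma, scale_sig)[, , 1]
    sigma <- chol2inv(chol(sig_inv))

    # --- gamma_i | . ~ N(S2 sum W' sig^-1 (y - M mu), S2)
    K <- lapply(seq_len(C), function(c)
      crossprod(ss$W[[c]], sig_inv %*% ss$W[[c]]))          # q x q
    B <- lapply(seq_len(C), function(c) crossprod(ss$W[[c]], sig_inv)) # q x 2
    U <- matrix(0, q, N)
    for (c in seq_len(C)) {
      U <- U + B[[c]] %*% rbind(ss$sumS[, c], ss$sumT[, c])
      U <- U - (B[[c]] %*% (ss$M[[c]] %*% mu)) %*% rbind(ss$ncount[, c])
    }
    for (g in groups) {
      nc <- ss$ncount[g[1], ]
      P <- Reduce(`+`, lapply(seq_len(C), function(c) nc[c] * K[[c]]))
      ch <- chol(P + D_inv)
      S2 <- chol2inv(ch)
      mean_g <- S2 %*% U[, g, drop = FALSE]
      Z <- matrix(stats::rnorm(q * length(g)), q)
      Gamma[g, ] <- t(mean_g + backsolve(ch, Z))
    }

    # --- mu | . ~ N(S3 sum M' sig^-1 (y - W gamma), S3)
    S3_inv <- Sigma0_inv
    rhs <- numeric(pf)
    for (c in seq_len(C)) {
      Msig <- crossprod(ss$M[[c]], sig_inv)                 # pf x 2
      S3_inv <- S3_inv + sum(ss$ncount[, c]) * (Msig %*% ss$M[[c]])
      gs <- colSums(ss$ncount[, c] * Gamma)
      SY <- c(sum(ss$sumS[, c]), sum(ss$sumT[, c]))
      rhs <- rhs + drop(Msig %*% (SY - ss$W[[c]] %*% gs))
    }
    ch3 <- chol(S3_inv)
    mu <- drop(chol2inv(ch3) %*% rhs + backsolve(ch3, stats::rnorm(pf)))

    if (!all(is.finite(mu)) || !all(is.finite(D)) || !all(is.finite(sigma)))
      stop("divergent chain: non-finite draw at iteration ", it, call. = FALSE)

    if (k < n_keep && it == keep_at[k + 1L]) {
      k <- k + 1L
      mu_out[k, ] <- mu
      D_out[, , k] <- D
      sigma_out[, , k] <- sigma
      if (store_gamma) gamma_out[, , k] <- Gamma
    }
  }
  list(mu = mu_out, D = D_out, sigma = sigma_out, gamma = gamma_out)
}

#' Fit the bivariate mixed model by conjugate Gibbs sampling
#'
#' Cycles the four conjugate full conditionals — D^-1 (Wishart), sigma^-1
#' (Wishart), the trial random effects (multivariate normal) and the fixed
#' effects (multivariate normal) — in that fixed order. Subjects with a
#' missing true endpoint are excluded from the fit (an ongoing trial's
#' partial data enters through [conditional_random_effects()] instead), and
#' trials with a single treatment arm are dropped with a warning.
#'
#' @param data meta-analytic dataset (see [read_meta()] for the layout).
#' @param scenario `"S1"` or `"S2"`.
#' @param prior an [sp_prior]; defaults to the reference priors.
#' @param iterations,burn_in,thinning MCMC settings (defaults 4000 / 1000 / 1).
#' @param chains number of chains; chain k seeds the generator with
#'   `seed + 104729 (k - 1)`.
#' @param seed integer seed; runs are bitwise-reproducible given the seed.
#' @param store_gamma keep the per-trial random-effect draws.
#' @return object of class `sp_draws`: `mu` (draws x p matrix), `D` and
#'   `sigma` (arrays with the draw index last), optional `gamma`, `chain`,
#'   plus scenario/prior/seed metadata.
#' @export
gibbs_fit <- function(data, scenario = c("S1", "S2"), prior = NULL,
                      iterations = 4000, burn_in = 1000, thinning = 1,
                      chains = 1, seed = 1L, store_gamma = FALSE) {
  scenario <- match.arg(scenario)
  stopifnot(iterations > burn_in, thinning >= 1, chains >= 1)
  data <- .validate_meta(data)
  p <- attr(data, "n_covariates")
  if (scenario == "S2" && p != 1)
    stop("scenario S2 requires exactly one covariate column", call. = FALSE)

  n_miss <- sum(is.na(data$t))
  if (n_miss > 0) {
    warning(n_miss, " subjects with missing T excluded from the fit",
            call. = FALSE)
    data <- data[!is.na(data$t), , drop = FALSE]
  }
  arms <- tapply(data$z, data$trial, function(z) length(unique(z)))
  bad <- names(arms)[arms < 2]
  if (length(bad)) {
    warning("dropping single-arm trial(s): ", paste(bad, collapse = ", "),
            call. = FALSE)
    data <- data[!(data$trial %in% bad), , drop = FALSE]
  }
  if (!nrow(data)) stop("no usable trials", call. = FALSE)

  q <- if (scenario == "S2") 8L else 4L
  pf <- 4L + 4L * p
  if (is.null(prior)) prior <- sp_prior(q, pf)
  stopifnot(inherits(prior, "sp_prior"), prior$q == q, prior$p_fixed == pf)

  ss <- .suffstats(data, scenario, p)
  res <- lapply(seq_len(chains), function(k)
    .gibbs_chain(ss, prior, iterations, burn_in, thinning, store_gamma,
                 seed = seed + 104729L * (k - 1L)))
  draws <- list(
    mu = do.call(rbind, lapply(res, `[[`, "mu")),
    D = array(unlist(lapply(res, `[[`, "D")),
              c(q, q, sum(vapply(res, function(r) dim(r$D)[3], 0)))),
    sigma = array(unlist(lapply(res, `[[`, "sigma")),
                  c(2, 2, sum(vapply(res, function(r) dim(r$sigma)[3], 0)))))
  if (store_gamma)
    draws$gamma <- array(unlist(lapply(res, `[[`, "gamma")),
                         c(ss$N, q, dim(draws$D)[3]))
  colnames(draws$mu) <- fixed_effect_names(p)
  n_per <- vapply(res, function(r) nrow(r$mu), 0L)
  structure(c(draws,
              list(chain = rep(seq_len(chains), n_per),
                   scenario = scenario, p = p, trials = ss$trials,
                   prior = prior, seed = seed,
                   iterations = iterations, burn_in = burn_in,
                   thinning = thinning)),
            class = "sp_draws")
}

#' @export
print.sp_draws <- function(x, ...) {
  cat(sprintf("Posterior draws (%s, %d retained, %d chain%s, seed %d)\n",
              x$scenario, nrow(x$mu), max(x$chain),
              if (max(x$chain) > 1) "s" else "", x$seed))
  cat("Fixed-effect posterior means:\n")
  print(round(colMeans(x$mu), 4))
  invisible(x)
}

#' @export
summary.sp_draws <- function(object, ...) {
  sm <- t(apply(object$mu, 2, function(v)
    c(mean = mean(v), sd = stats::sd(v),
      stats::quantile(v, c(.025, .5, .975)))))
  if (max(object$chain) >= 2) {
    rhat <- apply(object$mu, 2, .rhat, chain = object$chain)
    sm <- cbind(sm, Rhat = rhat)
  }
  sm
}

# split-free Gelman-Rubin statistic over whole chains
.rhat <- function(v, chain) {
  ch <- split(v, chain)
  m <- length(ch); n <- min(lengths(ch))
  ch <- lapply(ch, function(x) x[seq_len(n)])
  means <- vapply(ch, mean, 0); vars <- vapply(ch, stats::var, 0)
  B <- n * stats::var(means); Wv <- mean(vars)
  sqrt(((n - 1) / n * Wv + B / n) / Wv)
}

# internal: joint law of (Delta_S, Delta_T) from raw draw components
.joint_from_draw <- function(mu, D, scenario, p, x) {
  if (p > 0) {
    dS <- mu[4 + 2 * p + seq_len(p)]; dT <- mu[4 + 3 * p + seq_len(p)]
    m <- c(mu[3] + sum(dS * x), mu[4] + sum(dT * x))
  } else m <- mu[3:4]
  E <- .delta_contrast(scenario, if (scenario == "S2") x else 0)
  list(mean = m, cov = E %*% D %*% t(E))
}

#' Posterior distributions of the paradox-risk measures
#'
#' Applies the measure formulas to every retained draw and summarizes with
#' posterior means and equal-tailed credible intervals. The s-threshold is
#' computed only when arm counts are supplied; draws violating its
#' precondition (nonpositive surrogate-outcome covariance) are counted and
#' reported in `n_failed`, with a warning above a 5% failure rate.
#'
#' @param draws an `sp_draws` from [gibbs_fit()] (at least 100 retained
#'   draws).
#' @param x_levels covariate levels.
#' @param alpha risk level for the s-threshold.
#' @param n1x,n0x planning arm counts for the s-threshold; `NULL` skips s.
#' @param level credible level (default 0.95).
#' @return data frame with columns `measure`, `x`, `estimate`, `lower`,
#'   `upper`, `n_failed`; the per-draw values are kept in attribute
#'   `"draws"`.
#' @export
posterior_measures <- function(draws, x_levels = c(0, 1), alpha = 0.05,
                               n1x = NULL, n0x = NULL, level = 0.95) {
  stopifnot(inherits(draws, "sp_draws"))
  R <- nrow(draws$mu)
  if (R < 100) stop("need at least 100 retained draws", call. = FALSE)
  do_s <- !is.null(n1x) && !is.null(n0x)
  measures <- c("psi_sp13", "psi_sp123", if (do_s) "s")
  pr <- (1 - level) / 2
  out <- list(); per_draw <- list()
  for (x in x_levels) {
    vals <- matrix(NA_real_, R, length(measures),
                   dimnames = list(NULL, measures))
    for (r in seq_len(R)) {
      j <- .joint_from_draw(draws$mu[r, ], draws$D[, , r],
                            draws$scenario, draws$p, x)
      jj <- sp_joint(j$mean, j$cov)
      vals[r, "psi_sp13"] <- psi_sp13(jj)
      vals[r, "psi_sp123"] <- psi_sp123(jj)
      if (do_s) {
        dab <- j$cov[1, 2]
        if (dab > 0) {
          daa_t <- j$cov[1, 1] +
            draws$sigma[1, 1, r] * (1 / n1x + 1 / n0x)
          v <- j$cov[2, 2] - dab^2 / daa_t
          if (v > 0)
            vals[r, "s"] <- j$mean[1] - daa_t / dab *
              (stats::qnorm(alpha) * sqrt(v) + j$mean[2])
        }
      }
    }
    for (ms in measures) {
      v <- vals[, ms]; ok <- !is.na(v)
      if (ms == "s" && mean(!ok) > 0.05)
        warning(sprintf("s-threshold undefined for %.1f%% of draws at x=%s",
                        100 * mean(!ok), format(x)), call. = FALSE)
      out[[length(out) + 1]] <- data.frame(
        measure = ms, x = x, estimate = mean(v[ok]),
        lower = stats::quantile(v[ok], pr, names = FALSE),
        upper = stats::quantile(v[ok], 1 - pr, names = FALSE),
        n_failed = sum(!ok))
    }
    per_draw[[as.character(x)]] <- vals
  }
  res <- do.call(rbind, out)
  attr(res, "draws") <- per_draw
  attr(res, "level") <- level
  res
}

# Posterior propagation of the conditional (partial-data) measures: for
# each retained draw, predict the ongoing trial's random effects from its
# partial data and evaluate the conditional psi_SP13. Uses the same
# design-row collapse as the sampler, with a missing-T flag in the key.
.posterior_partial <- function(draws, part_data, x_levels, level = 0.95,
                               measure = "psi_sp13") {
  part_data <- .validate_meta(part_data, allow_missing_t = TRUE)
  p <- draws$p; scen <- draws$scenario
  q <- if (scen == "S2") 8L else 4L
  xcols <- grep("^x", names(part_data), value = TRUE)
  miss <- is.na(part_data$t)
  key <- do.call(paste, c(list(part_data$z), part_data[xcols],
                          list(miss, sep = "\r")))
  cidx <- !duplicated(key)
  cz <- part_data$z[cidx]
  cx <- if (p > 0) as.matrix(part_data[cidx, xcols, drop = FALSE]) else
    matrix(0, sum(cidx), 0)
  cmiss <- miss[cidx]
  ci <- match(key, key[cidx])
  C <- sum(cidx)
  nc <- tabulate(ci, C)
  sumS <- vapply(seq_len(C), function(c) sum(part_data$s[ci == c]), 0)
  sumT <- vapply(seq_len(C), function(c)
    if (cmiss[c]) 0 else sum(part_data$t[ci == c]), 0)
  Mc <- lapply(seq_len(C), function(c) .m_rows(p, cz[c], cx[c, ]))
  Wc <- lapply(seq_len(C), function(c) .w_rows(scen, cz[c], cx[c, ]))

  R <- nrow(draws$mu)
  pr <- (1 - level) / 2
  psi_fun <- if (measure == "psi_sp13") psi_sp13 else psi_sp123
  vals <- matrix(NA_real_, R, length(x_levels))
  for (r in seq_len(R)) {
    mu <- draws$mu[r, ]; D <- draws$D[, , r]; sig <- draws$sigma[, , r]
    diag(sig) <- pmax(diag(sig), 1e-8)
    sig_inv <- solve(sig)
    A <- matrix(0, q, q); u <- numeric(q)
    for (c in seq_len(C)) {
      keep <- if (cmiss[c]) 1L else 1:2
      Wk <- Wc[[c]][keep, , drop = FALSE]
      Rk_inv <- if (cmiss[c]) matrix(1 / sig[1, 1], 1, 1) else sig_inv
      WtRi <- crossprod(Wk, Rk_inv)
      A <- A + nc[c] * WtRi %*% Wk
      resid <- c(sumS[c], sumT[c])[keep] -
        nc[c] * drop(Mc[[c]][keep, , drop = FALSE] %*% mu)
      u <- u + drop(WtRi %*% resid)
    }
    sol <- solve(diag(q) + D %*% A, cbind(D %*% u, D))
    g <- sol[, 1]; Dt <- (sol[, -1] + t(sol[, -1])) / 2
    for (k in seq_along(x_levels)) {
      x <- x_levels[k]
      E <- .delta_contrast(scen, if (scen == "S2") x else 0)
      base <- .joint_from_draw(mu, D * 0, scen, p, x)$mean
      jj <- sp_joint(base + drop(E %*% g), E %*% Dt %*% t(E))
      vals[r, k] <- psi_fun(jj)
    }
  }
  data.frame(x = x_levels, estimate = colMeans(vals),
             lower = apply(vals, 2, stats::quantile, pr),
             upper = apply(vals, 2, stats::quantile, 1 - pr))
}

#' Conditional paradox-risk measure from posterior draws and partial data
#'
#' Per-draw propagation of [psi_sp13_partial()]: for every retained
#' posterior draw, the ongoing trial's random effects are predicted from
#' its partially collected data and the conditional measure is evaluated,
#' yielding a posterior distribution that reflects parameter uncertainty.
#'
#' @param draws an `sp_draws` from [gibbs_fit()] on the historical trials.
#' @param trial_data the ongoing trial's data (`t` may be `NA`).
#' @param x_levels covariate levels.
#' @param level credible level.
#' @param measure `"psi_sp13"` or `"psi_sp123"`.
#' @return data frame with `x`, `estimate`, `lower`, `upper`.
#' @export
posterior_partial_measures <- function(draws, trial_data, x_levels = c(0, 1),
                                       level = 0.95,
                                       measure = c("psi_sp13", "psi_sp123")) {
  stopifnot(inherits(draws, "sp_draws"))
  measure <- match.arg(measure)
  .posterior_partial(draws, trial_data, x_levels, level, measure)
}

#' Marginal WAIC of a fitted model
#'
#' Widely applicable information criterion on the deviance scale, computed
#' from the trial-level marginal likelihood: for each draw of (mu, D,
#' sigma) the random effects are integrated out analytically, giving a
#' multivariate normal likelihood with covariance W_i D W_i' + R_i per
#' trial. WAIC = -2 (lppd - p_waic) with the variance-based effective
#' parameter count; lower is better. Comparing the S1 and S2 fits of the
#' same data assesses the need for covariate random effects.
#'
#' @param draws an `sp_draws` from [gibbs_fit()].
#' @param data the dataset the model was fit to.
#' @return object of class `sp_waic`: list with `waic`, `lppd`, `p_waic`
#'   and the draws-by-trials `pointwise` log-likelihood matrix.
#' @export
marginal_waic <- function(draws, data) {
  stopifnot(inherits(draws, "sp_draws"))
  data <- .validate_meta(data)
  data <- data[!is.na(data$t), , drop = FALSE]
  p <- draws$p; scen <- draws$scenario
  q <- if (scen == "S2") 8L else 4L
  ss <- .suffstats(data, scen, p)
  R <- nrow(draws$mu)
  ll <- matrix(NA_real_, R, ss$N)
  for (r in seq_len(R)) {
    mu <- draws$mu[r, ]; D <- draws$D[, , r]; sig <- draws$sigma[, , r]
    sig_inv <- chol2inv(chol(sig))
    ld_sig <- determinant(sig, logarithm = TRUE)$modulus
    D_inv <- chol2inv(chol(D))
    ld_D <- determinant(D, logarithm = TRUE)$modulus
    K <- lapply(seq_len(ss$C), function(c)
      crossprod(ss$W[[c]], sig_inv %*% ss$W[[c]]))
    B <- lapply(seq_len(ss$C), function(c) crossprod(ss$W[[c]], sig_inv))
    m0 <- lapply(seq_len(ss$C), function(c) drop(ss$M[[c]] %*% mu))
    for (i in seq_len(ss$N)) {
      A <- matrix(0, q, q); u <- numeric(q)
      EE <- ss$YYtrial[, , i]
      for (c in seq_len(ss$C)) {
        n_ic <- ss$ncount[i, c]
        if (n_ic == 0) next
        sy <- c(ss$sumS[i, c], ss$sumT[i, c])
        A <- A + n_ic * K[[c]]
        u <- u + drop(B[[c]] %*% (sy - n_ic * m0[[c]]))
        EE <- EE - tcrossprod(sy, m0[[c]]) - tcrossprod(m0[[c]], sy) +
          n_ic * tcrossprod(m0[[c]])
      }
      cap <- D_inv + A
      ch <- chol(cap)
      quad <- sum(sig_inv * EE) -
        sum(backsolve(ch, u, transpose = TRUE)^2)
      ld <- ss$n_i[i] * ld_sig + ld_D +
        2 * sum(log(diag(ch)))
      ll[r, i] <- -ss$n_i[i] * log(2 * pi) - 0.5 * ld - 0.5 * quad
      if (!is.finite(ll[r, i]))
        stop("non-finite marginal log-likelihood (trial ", ss$trials[i],
             ", draw ", r, ")", call. = FALSE)
    }
  }
  lppd <- sum(apply(ll, 2, function(v) {
    m <- max(v); m + log(mean(exp(v - m)))
  }))
  p_waic <- sum(apply(ll, 2, function(v) if (length(v) > 1) stats::var(v) else 0))
  structure(list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic,
                 pointwise = ll),
            class = "sp_waic")
}

#' @export
print.sp_waic <- function(x, ...) {
  cat(sprintf("Marginal WAIC: %.2f (lppd %.2f, p_waic %.2f)\n",
              x$waic, x$lppd, x$p_waic))
  invisible(x)
}
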