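# Shared fixtures and independent oracles used across test files.

# Monte-Carlo quadrant frequencies for a bivariate normal law: the
# brute-force oracle for both orthant-probability measures.
mc_quadrants <- function(mean, cov, n = 2e5) {
  z <- mvtnorm::rmvnorm(n, mean = mean, sigma = cov)
  q1 <- mean(z[, 1] > 0 & z[, 2] > 0)
  q3 <- mean(z[, 1] < 0 & z[, 2] < 0)
  q4 <- mean(z[, 1] > 0 & z[, 2] < 0)
  list(psi13 = q1 + q3, psi123 = 1 - q4, n = n)
}

# binomial standard error for a Monte-Carlo proportion
binom_se <- function(p, n) sqrt(pmax(p * (1 - p), 1e-12) / n)

# a random valid 2x2 covariance via a random correlation
random_cov2 <- function() {
  v <- stats::runif(2, 0.2, 3)
  r <- stats::runif(1, -0.95, 0.95)
  matrix(c(v[1], r * sqrt(v[1] * v[2]), r * sqrt(v[1] * v[2]), v[2]), 2)
}

# small arbitrary (non-default) parameter sets used in several files
toy_params_s1 <- function() {
  D <- matrix(0.2, 4, 4); diag(D) <- c(1, 1.2, 0.8, 1.1); D[3, 4] <- D[4, 3] <- 0.4
  sp_params("S1",
            fixed = c(alpha_S = 0.5, alpha_T = -0.2, beta_S = 1.5, beta_T = 0.8,
                      gamma_S = 0.3, gamma_T = -0.1, delta_S = -0.6, delta_T = 0.5),
            D = D, sigma = matrix(c(0.9, 0.2, 0.2, 1.1), 2))
}

toy_params_s2 <- function() {
  D <- matrix(0.15, 8, 8); diag(D) <- 1; D[3, 4] <- D[4, 3] <- 0.45
  sp_params("S2",
            fixed = c(alpha_S = 1, alpha_T = 1, beta_S = 2, beta_T = 1,
                      gamma_S = 0, gamma_T = 0, delta_S = -1, delta_T = 1),
            D = D, sigma = matrix(c(1, 0.3, 0.3, 1), 2))
}

# Dense-matrix conditional moments of a trial's random effects: the
# textbook formula gamma | Y ~ N(D W' V^-1 (Y - M mu), D - D W' V^-1 W D)
# built on the fully stacked system (missing-T rows deleted). Independent
# of the package's Woodbury implementation.
dense_conditional <- function(params, trial_data) {
  p <- params$p; scen <- params$scenario
  q <- if (scen == "S2") 8L else 4L
  xcols <- grep("^x", names(trial_data), value = TRUE)
  Ms <- list(); Ws <- list(); ys <- list(); Rs <- list()
  for (i in seq_len(nrow(trial_data))) {
    z <- trial_data$z[i]
    x <- if (p > 0) as.numeric(trial_data[i, xcols, drop = TRUE]) else numeric(0)
    M <- surrosp:::.m_rows(p, z, x)
    W <- surrosp:::.w_rows(scen, z, x)
    y <- c(trial_data$s[i], trial_data$t[i])
    keep <- !is.na(y)
    Ms[[i]] <- M[keep, , drop = FALSE]
    Ws[[i]] <- W[keep, , drop = FALSE]
    ys[[i]] <- y[keep]
    Rs[[i]] <- params$sigma[keep, keep, drop = FALSE]
  }
  M <- do.call(rbind, Ms); W <- do.call(rbind, Ws); y <- unlist(ys)
  R <- matrix(0, length(y), length(y))
  at <- 1
  for (b in Rs) {
    k <- nrow(b)
    R[at:(at + k - 1), at:(at + k - 1)] <- b
    at <- at + k
  }
  V <- W %*% params$D %*% t(W) + R
  DWtVi <- params$D %*% t(W) %*% solve(V)
  list(gamma_tilde = unname(drop(DWtVi %*% (y - M %*% params$fixed))),
       D_tilde = unname(params$D - DWtVi %*% W %*% params$D))
}

# one-trial data frame with explicit (z, x, s, t) columns
trial_df <- function(z, x = NULL, s, t) {
  d <- data.frame(trial = "N", subject = seq_along(z), z = z, s = s, t = t)
  if (!is.null(x)) d$x <- x
  d[, c("trial", "subject", "z", if (!is.null(x)) "x", "s", "t")]
}
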