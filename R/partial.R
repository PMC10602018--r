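# Conditional prediction of an ongoing trial's random effects from its
# partially collected data (surrogate observed for everyone, true endpoint
# possibly missing), and the conditional paradox-risk measures.
#
# The joint of the stacked observations Y and the trial's random effects g
# is multivariate normal, so deleting the rows of missing T values is exact
# marginalization. With A = W' R^-1 W and u = W' R^-1 (Y - M mu), the
# conditional moments
#   g | Y ~ N(g_tilde, D_tilde),
#   g_tilde = D W' V^-1 (Y - M mu),  D_tilde = D - D W' V^-1 W D,
#   V = W D W' + R
# reduce by the Woodbury identity to
#   g_tilde = (I + D A)^-1 D u,  D_tilde = (I + D A)^-1 D,
# which needs only per-subject 2x2 (or 1x1) residual blocks: O(n) work.

# Per-subject fixed-effect design rows: S row then T row.
.m_rows <- function(p, z, x) {
  M <- matrix(0, 2, 4 + 4 * p)
  M[1, 1] <- 1; M[1, 3] <- z
  M[2, 2] <- 1; M[2, 4] <- z
  if (p > 0) {
    for (k in seq_len(p)) {
      M[1, 4 + k] <- x[k];           M[2, 4 + p + k] <- x[k]
      M[1, 4 + 2 * p + k] <- x[k] * z; M[2, 4 + 3 * p + k] <- x[k] * z
    }
  }
  M
}

# Per-subject random-effect design rows; covariate columns only under S2.
.w_rows <- function(scenario, z, x) {
  if (scenario == "S2") .m_rows(1, z, x) else .m_rows(0, z, numeric(0))
}

# Accumulate A = sum W' R^-1 W and u = sum W' R^-1 (y - M mu) over subjects,
# dropping the T row where T is missing (residual block sigma_ss only).
.partial_stats <- function(params, trial_data) {
  p <- params$p; scen <- params$scenario
  q <- if (scen == "S2") 8L else 4L
  sig <- params$sigma
  diag(sig) <- pmax(diag(sig), 1e-8)   # residual-variance floor
  sig_inv <- solve(sig)
  A <- matrix(0, q, q); u <- numeric(q)
  n_obs <- 0L; n_missing_t <- 0L
  xcols <- grep("^x", names(trial_data), value = TRUE)
  for (i in seq_len(nrow(trial_data))) {
    z <- trial_data$z[i]
    x <- if (p > 0) as.numeric(trial_data[i, xcols, drop = TRUE]) else numeric(0)
    M <- .m_rows(p, z, x)
    W <- .w_rows(scen, z, x)
    y <- c(trial_data$s[i], trial_data$t[i])
    keep <- !is.na(y)
    if (!keep[1]) stop("surrogate S may not be missing", call. = FALSE)
    if (!keep[2]) n_missing_t <- n_missing_t + 1L
    Mk <- M[keep, , drop = FALSE]; Wk <- W[keep, , drop = FALSE]
    Rk_inv <- if (all(keep)) sig_inv else matrix(1 / sig[1, 1], 1, 1)
    WtRi <- crossprod(Wk, Rk_inv)
    A <- A + WtRi %*% Wk
    u <- u + drop(WtRi %*% (y[keep] - Mk %*% params$fixed))
    n_obs <- n_obs + 1L
  }
  list(A = A, u = u, n_obs = n_obs, n_missing_t = n_missing_t)
}

#' Conditional distribution of an ongoing trial's random effects
#'
#' Predicts the trial-level random effects of a trial from its (possibly
#' partial) subject data, given historical model parameters: the best
#' linear unbiased predictor and its conditional covariance under the
#' bivariate mixed model. Subjects with a missing true endpoint contribute
#' only their surrogate row, which — the joint being multivariate normal —
#' is exactly the marginalization of the unobserved T values.
#'
#' @param params an [sp_params] object (point estimates or one posterior
#'   draw).
#' @param trial_data data frame with columns `z`, `s`, `t` (NA allowed in
#'   `t`) and covariate column(s) `x`/`x1`... as required by the scenario;
#'   zero rows returns the prior (`gamma_tilde = 0`, `D_tilde = D`).
#' @return object of class `sp_conditional`: list with `gamma_tilde`
#'   (named length-4/8 vector), `D_tilde`, `n_obs`, `n_missing_t`.
#' @export
conditional_random_effects <- function(params, trial_data) {
  stopifnot(inherits(params, "sp_params"))
  q <- if (params$scenario == "S2") 8L else 4L
  labs <- .re_labels(params$scenario)
  if (is.null(trial_data) || nrow(trial_data) == 0) {
    g <- stats::setNames(numeric(q), labs)
    return(structure(list(gamma_tilde = g, D_tilde = params$D,
                          n_obs = 0L, n_missing_t = 0L),
                     class = "sp_conditional"))
  }
  st <- .partial_stats(params, trial_data)
  B <- diag(q) + params$D %*% st$A
  sol <- tryCatch(solve(B, cbind(params$D %*% st$u, params$D)),
                  error = function(e)
                    stop("conditioning system numerically singular; ",
                         "consider raising the residual-variance floor",
                         call. = FALSE))
  g <- stats::setNames(drop(sol[, 1]), labs)
  Dt <- sol[, -1, drop = FALSE]
  Dt <- (Dt + t(Dt)) / 2
  dimnames(Dt) <- list(labs, labs)
  structure(list(gamma_tilde = g, D_tilde = Dt,
                 n_obs = st$n_obs, n_missing_t = st$n_missing_t),
            class = "sp_conditional")
}

#' @export
print.sp_conditional <- function(x, ...) {
  cat(sprintf("Conditional random effects (n = %d subjects, %d missing T)\n",
              x$n_obs, x$n_missing_t))
  print(round(x$gamma_tilde, 4))
  invisible(x)
}

#' Conditional treatment-effect law for an ongoing trial
#'
#' Combines historical fixed effects with the trial's predicted random
#' effects into the conditional bivariate law of (Delta_S(x), Delta_T(x)):
#' mean \eqn{\beta + \delta x + \tilde b + x \tilde d} and covariance
#' \eqn{E \tilde D E^T} for the (1, x)-pattern contrast E over the
#' (bS, bT[, dS, dT]) block (under S1 the x-weighted terms are absent).
#'
#' @inheritParams conditional_random_effects
#' @param cond an `sp_conditional` from [conditional_random_effects()].
#' @param x covariate level.
#' @return an [sp_joint].
#' @export
conditional_joint <- function(params, cond, x = numeric(0)) {
  stopifnot(inherits(cond, "sp_conditional"))
  x <- as.numeric(x)
  if (length(x) != params$p)
    stop(sprintf("'x' must have length %d", params$p), call. = FALSE)
  E <- .delta_contrast(params$scenario, if (params$scenario == "S2") x else 0)
  m <- .delta_mean(params$fixed, params$p, x) + drop(E %*% cond$gamma_tilde)
  V <- E %*% cond$D_tilde %*% t(E)
  sp_joint(m, V, x = x)
}

#' Conditional paradox-risk measures for an ongoing trial
#'
#' psi_SP13 (and psi_SP123) for a trial that has already collected part of
#' its data, conditioning the trial's random effects on those observations.
#' With no data they reduce exactly to the unconditional measures.
#'
#' @inheritParams conditional_joint
#' @return probability.
#' @export
psi_sp13_partial <- function(params, cond, x = numeric(0)) {
  psi_sp13(conditional_joint(params, cond, x))
}

#' @rdname psi_sp13_partial
#' @export
psi_sp123_partial <- function(params, cond, x = numeric(0)) {
  psi_sp123(conditional_joint(params, cond, x))
}
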