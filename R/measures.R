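# Surrogate-paradox risk measures computed from the bivariate-normal law of
# the trial-level treatment effects (Delta_S, Delta_T).

# Phi_1(0; m, v): P(X <= 0) for X ~ N(m, v), allowing v = 0 away from m = 0.
.phi1_0 <- function(m, v) {
  if (v > 0) return(stats::pnorm(0, mean = m, sd = sqrt(v)))
  if (m == 0)
    stop("degenerate margin: zero variance with mean exactly 0 (sign undefined)",
         call. = FALSE)
  as.numeric(m < 0)
}

# Phi_2((0,0); m, V): P(X <= 0, Y <= 0), robust to (near-)singular V.
.phi2_00 <- function(m, V) {
  s1 <- sqrt(V[1, 1]); s2 <- sqrt(V[2, 2])
  if (s1 == 0) return(.phi1_0(m[1], 0) * .phi1_0(m[2], V[2, 2]))
  if (s2 == 0) return(.phi1_0(m[2], 0) * .phi1_0(m[1], V[1, 1]))
  rho <- V[1, 2] / (s1 * s2)
  a1 <- -m[1] / s1; a2 <- -m[2] / s2
  if (rho >= 1 - 1e-12) return(stats::pnorm(min(a1, a2)))
  if (rho <= -1 + 1e-12) return(max(0, stats::pnorm(a1) - stats::pnorm(-a2)))
  mvtnorm::pmvnorm(upper = c(a1, a2), corr = matrix(c(1, rho, rho, 1), 2),
                   algorithm = mvtnorm::TVPACK(abseps = 1e-10))[1]
}

.clamp01 <- function(p, slack = 1e-10) {
  if (p < -slack || p > 1 + slack)
    stop(sprintf("probability %g outside [0,1] beyond numerical slack", p),
         call. = FALSE)
  min(max(p, 0), 1)
}

.as_joint <- function(joint, x) {
  if (inherits(joint, "sp_params")) joint_effect_distribution(joint, x)
  else { stopifnot(inherits(joint, "sp_joint")); joint }
}

#' Probability of sign agreement in a new trial (psi_SP13)
#'
#' Probability that the next trial's treatment effects on the surrogate and
#' the true endpoint have the same sign, i.e. that (Delta_S, Delta_T) falls
#' in quadrant I or III:
#' \deqn{\Psi_{SP13} = P(\Delta_S \Delta_T > 0)
#'   = 1 - \Phi_1(0; m_S, v_{SS}) - \Phi_1(0; m_T, v_{TT})
#'   + 2\,\Phi_2((0,0); m, V)}
#'
#' @param joint an [sp_joint] object, or an [sp_params] object together
#'   with `x`.
#' @param x covariate profile, used only when `joint` is an [sp_params].
#' @return probability in \[0, 1\].
#' @examples
#' psi_sp13(sp_joint(c(2, 1), matrix(c(1, .375, .375, .5), 2)))
#' @export
psi_sp13 <- function(joint, x = numeric(0)) {
  j <- .as_joint(joint, x)
  p00 <- .phi2_00(j$mean, j$cov)
  .clamp01(1 - .phi1_0(j$mean[1], j$cov[1, 1]) -
             .phi1_0(j$mean[2], j$cov[2, 2]) + 2 * p00)
}

#' Probability of avoiding the dangerous surrogate paradox (psi_SP123)
#'
#' Probability that the next trial does not land in quadrant IV (surrogate
#' effect beneficial, true effect harmful):
#' \deqn{\Psi_{SP123} = 1 - P(\Delta_S > 0, \Delta_T < 0)
#'   = 1 - \Phi_1(0; m_T, v_{TT}) + \Phi_2((0,0); m, V)}
#'
#' @inheritParams psi_sp13
#' @return probability in \[0, 1\].
#' @export
psi_sp123 <- function(joint, x = numeric(0)) {
  j <- .as_joint(joint, x)
  .clamp01(1 - .phi1_0(j$mean[2], j$cov[2, 2]) + .phi2_00(j$mean, j$cov))
}

#' Both paradox-risk measures over a set of covariate levels
#'
#' @param params an [sp_params] object.
#' @param x_levels covariate levels; a numeric vector (one covariate) or a
#'   list of profiles.
#' @return data frame with columns `x`, `psi_sp13`, `psi_sp123`.
#' @export
paradox_measures <- function(params, x_levels = c(0, 1)) {
  if (!is.list(x_levels)) x_levels <- as.list(x_levels)
  rows <- lapply(x_levels, function(x) {
    j <- joint_effect_distribution(params, x)
    data.frame(x = paste(x, collapse = ","),
               psi_sp13 = psi_sp13(j), psi_sp123 = psi_sp123(j))
  })
  do.call(rbind, rows)
}

#' Observed surrogate treatment effect within a covariate level
#'
#' Arm-mean difference of the surrogate, O_Si(x), among subjects of trial
#' `trial` with covariate value `x`; the observable stand-in for Delta_S
#' used by the s-threshold machinery. When `params` is supplied, the
#' sampling-inflated variance \eqn{\tilde d_{aa} = d_{aa}^* +
#' \sigma_{ss}(1/n_{1x} + 1/n_{0x})} is attached.
#'
#' @param data a meta-analytic dataset (see [read_meta()]).
#' @param trial trial identifier.
#' @param x covariate level to restrict to, or `NULL` for all subjects.
#' @param params optional [sp_params] for the variance computation.
#' @return list with `trial`, `x`, `o_s`, `n1x`, `n0x` and (if `params`
#'   given) `d_aa_tilde`.
#' @export
observed_surrogate_effect <- function(data, trial, x = NULL, params = NULL) {
  rows <- data[data$trial == trial, , drop = FALSE]
  if (!nrow(rows)) stop("no subjects for trial '", trial, "'", call. = FALSE)
  if (!is.null(x)) {
    if (!("x" %in% names(rows)))
      stop("dataset has no covariate column 'x'", call. = FALSE)
    rows <- rows[rows$x == x, , drop = FALSE]
  }
  n1 <- sum(rows$z == 1); n0 <- sum(rows$z == 0)
  if (n1 < 1 || n0 < 1)
    stop(sprintf("trial '%s'%s has an empty arm (n1=%d, n0=%d)", trial,
                 if (is.null(x)) "" else sprintf(" at x=%s", format(x)),
                 n1, n0), call. = FALSE)
  o_s <- mean(rows$s[rows$z == 1]) - mean(rows$s[rows$z == 0])
  out <- list(trial = trial, x = x, o_s = o_s, n1x = n1, n0x = n0)
  if (!is.null(params)) {
    j <- joint_effect_distribution(params, if (is.null(x)) numeric(0) else x)
    out$d_aa_tilde <- j$cov[1, 1] + params$sigma[1, 1] * (1 / n1 + 1 / n0)
  }
  out
}

# Shared core: conditional law of Delta_T given O_S = s at level x.
.harm_cond <- function(joint, sigma_ss, n1x, n0x) {
  d_aa_tilde <- joint$cov[1, 1] + sigma_ss * (1 / n1x + 1 / n0x)
  v <- joint$cov[2, 2] - joint$cov[1, 2]^2 / d_aa_tilde
  if (v <= 0)
    stop("nonpositive conditional variance of Delta_T given O_S (degenerate D)",
         call. = FALSE)
  list(m = unname(joint$mean), dab = joint$cov[1, 2],
       d_aa_tilde = d_aa_tilde, v = v)
}

#' Probability of a harmful true effect given an observed surrogate effect
#'
#' \eqn{P(\Delta_T < 0 \mid O_S = s, X = x)} under the bivariate-normal law
#' of the observed surrogate arm-difference and the true treatment effect:
#' \deqn{\Phi\!\left(-\frac{m_T + (d_{ab}^*/\tilde d_{aa})(s - m_S)}
#'   {\sqrt{d_{bb}^* - (d_{ab}^*)^2/\tilde d_{aa}}}\right)}
#' with \eqn{\tilde d_{aa} = d_{aa}^* + \sigma_{ss}(1/n_{1x} + 1/n_{0x})}.
#'
#' @param params an [sp_params] object.
#' @param x covariate level.
#' @param s observed surrogate arm-mean difference.
#' @param n1x,n0x treated/control counts at level `x` (planning values for a
#'   prospective calculation, or counts from data for a retrospective one).
#' @return probability.
#' @export
prob_harm_given_s <- function(params, x, s, n1x, n0x) {
  stopifnot(n1x >= 1, n0x >= 1)
  j <- joint_effect_distribution(params, x)
  h <- .harm_cond(j, params$sigma[1, 1], n1x, n0x)
  unname(stats::pnorm(-(h$m[2] + h$dab / h$d_aa_tilde * (s - h$m[1])) /
                        sqrt(h$v)))
}

#' Surrogate-effect threshold bounding the probability of harm
#'
#' The smallest observed surrogate effect s such that
#' \eqn{P(\Delta_T < 0 \mid O_S = s, X = x) \le \alpha}. Computed by
#' monotone root-finding on the conditional probability, and cross-checked
#' against the closed form
#' \deqn{s^* = m_S - \frac{\tilde d_{aa}}{d_{ab}^*}
#'   \left(\Phi^{-1}(\alpha)\sqrt{d_{bb}^* - (d_{ab}^*)^2/\tilde d_{aa}}
#'   + m_T\right).}
#' Requires a positive surrogate-outcome effect association
#' (\eqn{d_{ab}^* > 0}), without which the threshold direction is reversed.
#'
#' @inheritParams prob_harm_given_s
#' @param alpha preset risk level in (0, 1); default 0.05.
#' @return object of class `sp_svalue`: list with `s` (root-finder value),
#'   `s_closed_form`, `alpha`, `x`, `n1x`, `n0x` and `prob_at_s`, a function
#'   evaluating the conditional harm probability at any s.
#' @export
s_threshold <- function(params, x, alpha = 0.05, n1x, n0x) {
  stopifnot(alpha > 0, alpha < 1, n1x >= 1, n0x >= 1)
  j <- joint_effect_distribution(params, x)
  h <- .harm_cond(j, params$sigma[1, 1], n1x, n0x)
  if (h$dab <= 0)
    stop("dab* <= 0: surrogate-outcome association nonpositive, ",
         "threshold direction undefined/reversed", call. = FALSE)
  s_cf <- h$m[1] - h$d_aa_tilde / h$dab *
    (stats::qnorm(alpha) * sqrt(h$v) + h$m[2])
  f <- function(s) prob_harm_given_s(params, x, s, n1x, n0x) - alpha
  half <- max(1, abs(s_cf) * 0.5)
  lo <- s_cf - half; hi <- s_cf + half
  while (f(lo) < 0) lo <- lo - half   # f is decreasing in s
  while (f(hi) > 0) hi <- hi + half
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  structure(list(s = root, s_closed_form = s_cf, alpha = alpha, x = x,
                 n1x = n1x, n0x = n0x,
                 prob_at_s = function(s) prob_harm_given_s(params, x, s, n1x, n0x)),
            class = "sp_svalue")
}

#' @export
print.sp_svalue <- function(x, ...) {
  cat(sprintf("s-threshold at x = %s, alpha = %g: s = %.4f (n1 = %d, n0 = %d)\n",
              format(x$x), x$alpha, x$s, x$n1x, x$n0x))
  invisible(x)
}

#' Covariate-averaged (marginal) paradox-risk measure
#'
#' Sample-average approximation of the covariate-marginalized measure,
#' \eqn{\Psi = \int \Psi(x)\,P(x)\,dx \approx \sum_i w_i \Psi(x_i)} with
#' empirical point masses w at the observed covariate values.
#'
#' @param psi numeric vector of per-level measure values.
#' @param weights nonnegative weights summing to 1; default equal weights
#'   (one mass per observed covariate value).
#' @return weighted average, inside `[min(psi), max(psi)]`.
#' @export
marginal_psi <- function(psi, weights = NULL) {
  psi <- as.numeric(psi)
  if (!length(psi)) stop("empty 'psi'", call. = FALSE)
  if (is.null(weights)) weights <- rep(1 / length(psi), length(psi))
  if (length(weights) != length(psi) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop("'weights' must be nonnegative and sum to 1", call. = FALSE)
  sum(psi * weights)
}
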