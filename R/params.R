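# Model parameters for the bivariate surrogate/true-endpoint mixed model.
#
# Random-effect ordering is fixed throughout the package:
#   Scenario 1 (S1): (aS, aT, bS, bT)                 -- 4 effects
#   Scenario 2 (S2): (aS, aT, bS, bT, cS, cT, dS, dT) -- 8 effects
# where a = trial intercept, b = trial treatment effect, c = trial covariate
# effect, d = trial covariate-by-treatment interaction, each for the
# surrogate (S) and true endpoint (T).

RE_LABELS_S1 <- c("aS", "aT", "bS", "bT")
RE_LABELS_S2 <- c(RE_LABELS_S1, "cS", "cT", "dS", "dT")

# Flat single-letter notation used in the field for D entries:
# Var(aS)=dss, Cov(bS,bT)=dab, Var(dS)=d_ds_ds, ...
RE_FLAT <- c(aS = "s", aT = "t", bS = "a", bT = "b",
             cS = "cs", cT = "ct", dS = "ds", dT = "dt")

.is_symmetric <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol * max(1, max(abs(m)))
}

.check_psd <- function(m, name, tol = 1e-8) {
  if (!.is_symmetric(m))
    stop(sprintf("'%s' must be a symmetric matrix", name), call. = FALSE)
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(abs(ev))))
    stop(sprintf("'%s' is not positive semidefinite (min eigenvalue %.3e)",
                 name, min(ev)), call. = FALSE)
  invisible(TRUE)
}

#' Fixed-effect names for a given number of covariates
#'
#' The fixed-effect vector is ordered (alpha_S, alpha_T, beta_S, beta_T,
#' gamma_S*, gamma_T*, delta_S*, delta_T*), matching the columns of the
#' per-subject design matrix.
#'
#' @param p number of covariates.
#' @return character vector of length `4 + 4 p`.
#' @export
fixed_effect_names <- function(p) {
  base <- c("alpha_S", "alpha_T", "beta_S", "beta_T")
  if (p == 0) return(base)
  suf <- if (p == 1) "" else paste0("_", seq_len(p))
  c(base,
    paste0("gamma_S", suf), paste0("gamma_T", suf),
    paste0("delta_S", suf), paste0("delta_T", suf))
}

.re_labels <- function(scenario) {
  if (scenario == "S2") RE_LABELS_S2 else RE_LABELS_S1
}

#' Model parameters for the bivariate mixed model
#'
#' Bundles the fixed effects, the trial-level random-effect covariance `D`
#' and the residual covariance `sigma` of the bivariate linear mixed model
#' for surrogate S and true endpoint T, under one of two covariate scenarios:
#' \describe{
#'   \item{S1}{covariate effects constant across trials; `D` is 4x4 over
#'     (aS, aT, bS, bT); any number of covariates (including 0, the
#'     unadjusted model).}
#'   \item{S2}{covariate effects vary across trials; exactly one scalar or
#'     binary covariate; `D` is 8x8 over (aS, aT, bS, bT, cS, cT, dS, dT).}
#' }
#'
#' @param scenario `"S1"` or `"S2"`.
#' @param fixed named numeric vector in the order given by
#'   [fixed_effect_names()]; names are checked when present.
#' @param D random-effect covariance matrix, 4x4 (S1) or 8x8 (S2).
#' @param sigma 2x2 residual covariance of the (S, T) errors.
#' @return an object of class `sp_params`.
#' @examples
#' p <- sp_params("S1",
#'   fixed = c(alpha_S = 1, alpha_T = 1, beta_S = 2, beta_T = 1,
#'             gamma_S = 0, gamma_T = 0, delta_S = -1, delta_T = 1),
#'   D = diag(4), sigma = diag(2))
#' joint_effect_distribution(p, x = 1)
#' @export
sp_params <- function(scenario = c("S1", "S2"), fixed, D, sigma) {
  scenario <- match.arg(scenario)
  fixed <- unlist(fixed)
  if ((length(fixed) - 4) %% 4 != 0 || length(fixed) < 4)
    stop("'fixed' must have length 4 + 4*p for p covariates", call. = FALSE)
  p <- (length(fixed) - 4L) %/% 4L
  if (scenario == "S2" && p != 1)
    stop("Scenario S2 supports exactly one scalar or binary covariate", call. = FALSE)
  nm <- fixed_effect_names(p)
  if (!is.null(names(fixed)) && any(nzchar(names(fixed))) &&
      !identical(names(fixed), nm))
    stop("fixed-effect names must be, in order: ", paste(nm, collapse = ", "),
         call. = FALSE)
  names(fixed) <- nm

  q <- if (scenario == "S2") 8L else 4L
  D <- as.matrix(D)
  if (!identical(dim(D), c(q, q)))
    stop(sprintf("'D' must be %dx%d under scenario %s", q, q, scenario),
         call. = FALSE)
  .check_psd(D, "D")
  if (any(diag(D) < 0)) stop("'D' has a negative diagonal entry", call. = FALSE)
  dimnames(D) <- list(.re_labels(scenario), .re_labels(scenario))

  sigma <- as.matrix(sigma)
  if (!identical(dim(sigma), c(2L, 2L)))
    stop("'sigma' must be 2x2", call. = FALSE)
  .check_psd(sigma, "sigma")
  dimnames(sigma) <- list(c("S", "T"), c("S", "T"))

  structure(list(scenario = scenario, p = p, fixed = fixed,
                 D = (D + t(D)) / 2, sigma = (sigma + t(sigma)) / 2),
            class = "sp_params")
}

#' @export
print.sp_params <- function(x, ...) {
  cat(sprintf("Bivariate mixed-model parameters (scenario %s, %d covariate%s)\n",
              x$scenario, x$p, if (x$p == 1) "" else "s"))
  cat("Fixed effects:\n")
  print(round(x$fixed, 4))
  cat("Random-effect covariance D:\n")
  print(round(x$D, 4))
  cat("Residual covariance sigma:\n")
  print(round(x$sigma, 4))
  invisible(x)
}

# Contrast matrix mapping random effects to (Delta_S(x), Delta_T(x)):
# Delta_S(x) = beta_S + delta_S x + bS (+ x dS under S2), likewise for T.
.delta_contrast <- function(scenario, x) {
  q <- if (scenario == "S2") 8L else 4L
  E <- matrix(0, 2, q, dimnames = list(c("S", "T"), .re_labels(scenario)))
  E["S", "bS"] <- 1
  E["T", "bT"] <- 1
  if (scenario == "S2") {
    E["S", "dS"] <- x
    E["T", "dT"] <- x
  }
  E
}

# Mean of (Delta_S(x), Delta_T(x)) from a fixed-effect vector.
.delta_mean <- function(fixed, p, x) {
  if (p == 0) return(c(S = unname(fixed[3]), T = unname(fixed[4])))
  dS <- fixed[4 + 2 * p + seq_len(p)]
  dT <- fixed[4 + 3 * p + seq_len(p)]
  c(S = unname(fixed[3] + sum(dS * x)), T = unname(fixed[4] + sum(dT * x)))
}

#' Joint distribution of the treatment effects at a covariate profile
#'
#' Computes the bivariate-normal law of the trial-level treatment effects
#' (Delta_S(x), Delta_T(x)) for a future trial among subjects with covariate
#' value `x`. Under S1 the covariate induces a pure mean shift
#' (beta + delta x) with the (bS, bT) covariance block unchanged; under S2
#' the trial-varying interaction effects additionally inflate the covariance:
#' \deqn{daa^* = daa + x^2 d_{ds,ds} + 2 x d_{a,ds}}
#' \deqn{dab^* = dab + x d_{a,dt} + x d_{b,ds} + x^2 d_{ds,dt}}
#' \deqn{dbb^* = dbb + x^2 d_{dt,dt} + 2 x d_{b,dt}}
#'
#' @param params an [sp_params] object.
#' @param x covariate profile: numeric of length `params$p` (a single real
#'   value under S2; may be any real number, not only 0/1).
#' @return an [sp_joint] object with elements `mean`, `cov`, `x`.
#' @export
joint_effect_distribution <- function(params, x = numeric(0)) {
  stopifnot(inherits(params, "sp_params"))
  x <- as.numeric(x)
  if (length(x) != params$p)
    stop(sprintf("'x' must have length %d (scenario %s)", params$p,
                 params$scenario), call. = FALSE)
  m <- .delta_mean(params$fixed, params$p, x)
  E <- .delta_contrast(params$scenario, if (params$scenario == "S2") x else 0)
  V <- E %*% params$D %*% t(E)
  sp_joint(m, V, x = x)
}

#' Bivariate treatment-effect distribution
#'
#' Container for the bivariate-normal law of (Delta_S, Delta_T); the input
#' to all paradox-risk measures. Usually produced by
#' [joint_effect_distribution()], but can be built directly from any mean
#' and covariance (e.g. values reported in a publication).
#'
#' @param mean numeric length-2 mean (E Delta_S, E Delta_T).
#' @param cov 2x2 symmetric positive-semidefinite covariance.
#' @param x optional covariate profile the law refers to.
#' @return an object of class `sp_joint`.
#' @export
sp_joint <- function(mean, cov, x = NULL) {
  mean <- as.numeric(mean)
  stopifnot(length(mean) == 2)
  cov <- as.matrix(cov)
  if (!identical(dim(cov), c(2L, 2L)))
    stop("'cov' must be 2x2", call. = FALSE)
  if (!.is_symmetric(cov))
    stop("'cov' must be symmetric", call. = FALSE)
  cov <- (cov + t(cov)) / 2
  if (any(diag(cov) < 0) ||
      cov[1, 1] * cov[2, 2] - cov[1, 2]^2 < -1e-10 * max(1, max(abs(cov)))^2)
    stop("'cov' is not positive semidefinite: invalid parameter set", call. = FALSE)
  names(mean) <- c("S", "T")
  dimnames(cov) <- list(c("S", "T"), c("S", "T"))
  structure(list(mean = mean, cov = cov, x = x), class = "sp_joint")
}

#' @export
print.sp_joint <- function(x, ...) {
  cat("Joint law of (Delta_S, Delta_T)")
  if (!is.null(x$x) && length(x$x)) cat(" at x =", paste(x$x, collapse = ", "))
  cat("\n  mean:", sprintf("(%.4f, %.4f)", x$mean[1], x$mean[2]), "\n")
  cat(sprintf("  cov : [[%.4f, %.4f], [%.4f, %.4f]]\n",
              x$cov[1, 1], x$cov[1, 2], x$cov[2, 1], x$cov[2, 2]))
  invisible(x)
}

#' Trial-level surrogacy measure R^2_trial
#'
#' Proportion of the between-trial variance of the treatment effect on the
#' true endpoint explained by the surrogate-related random effects
#' (aS, bS):
#' \deqn{R^2_{trial} = (d_{sb}\; d_{ab})
#'   \begin{pmatrix} d_{ss} & d_{sa} \\ d_{sa} & d_{aa} \end{pmatrix}^{-1}
#'   (d_{sb}\; d_{ab})^T / d_{bb}}
#'
#' @param D either an [sp_params] object or a random-effect covariance
#'   matrix whose leading 4x4 block is ordered (aS, aT, bS, bT).
#' @return scalar in \[0, 1\].
#' @export
rtrial2 <- function(D) {
  if (inherits(D, "sp_params")) D <- D$D
  D <- as.matrix(D)
  stopifnot(nrow(D) >= 4)
  v <- c(D[1, 4], D[3, 4])              # Cov(aS,bT), Cov(bS,bT)
  B <- D[c(1, 3), c(1, 3)]              # Var of (aS, bS)
  if (abs(det(B)) < 1e-12 * max(1, max(abs(B)))^2)
    stop("singular (aS, bS) covariance block", call. = FALSE)
  drop(crossprod(v, solve(B, v))) / D[4, 4]
}
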