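# Orthant-probability paradox measures, the observed surrogate effect, the
# conditional harm probability and the s-threshold.

test_that("published reference values are reproduced to three decimals", {
  cases <- list(
    list(m = c(2, 1), V = matrix(c(1, .375, .375, .5), 2),
         psi13 = 0.918, psi123 = 0.931),
    list(m = c(1, 2), V = matrix(c(1, .75, .75, 1), 2),
         psi13 = 0.858, psi123 = 0.997),
    list(m = c(.5, .5), V = matrix(c(1, .9, .9, 1), 2),
         psi13 = 0.874, psi123 = 0.937),
    list(m = c(3, 3), V = matrix(c(1, .25, .25, 1), 2),
         psi13 = 0.997, psi123 = 0.999))
  for (cs in cases) {
    j <- sp_joint(cs$m, cs$V)
    expect_equal(psi_sp13(j), cs$psi13, tolerance = 1e-3)
    expect_equal(psi_sp123(j), cs$psi123, tolerance = 1e-3)
  }
})

test_that("limiting and symmetric cases behave analytically", {
  # independent symmetric signs: psi13 = 2 * 0.25
  expect_equal(psi_sp13(sp_joint(c(0, 0), diag(2))), 0.5)
  # a strongly beneficial true effect precludes the dangerous quadrant
  expect_equal(psi_sp123(sp_joint(c(0, 10), diag(2))), 1, tolerance = 1e-6)
  # swapping the endpoints leaves psi13 invariant (quadrant symmetry)
  set.seed(2)
  for (i in 1:20) {
    m <- stats::runif(2, -2, 2); V <- random_cov2()
    expect_equal(psi_sp13(sp_joint(m, V)),
                 psi_sp13(sp_joint(rev(m), V[2:1, 2:1])), tolerance = 1e-9)
  }
  # degenerate margin with mean 0 is an error, not a silent answer
  expect_error(psi_sp13(sp_joint(c(0, 1), diag(c(0, 1)))), "sign undefined")
})

test_that("measures agree with Monte-Carlo quadrant frequencies", {
  set.seed(7)
  for (i in 1:5) {
    m <- stats::runif(2, -1.5, 1.5); V <- random_cov2()
    j <- sp_joint(m, V)
    mc <- mc_quadrants(m, V, n = 2e5)
    expect_lt(abs(psi_sp13(j) - mc$psi13), 4 * binom_se(mc$psi13, mc$n))
    expect_lt(abs(psi_sp123(j) - mc$psi123), 4 * binom_se(mc$psi123, mc$n))
  }
})

test_that("psi_sp123 dominates psi_sp13 and both respond to the mean as expected", {
  set.seed(3)
  for (i in 1:50) {
    j <- sp_joint(stats::runif(2, -3, 3), random_cov2())
    expect_gte(psi_sp123(j) + 1e-12, psi_sp13(j))
  }
  V <- random_cov2()
  vals <- vapply(seq(-2, 2, by = .5),
                 function(mt) psi_sp123(sp_joint(c(1, mt), V)), 0)
  expect_true(all(diff(vals) >= -1e-12))   # nondecreasing in m_T
  expect_gt(psi_sp13(sp_joint(c(8, 8), V)), 0.999)
})

test_that("observed surrogate effect is the within-level arm-mean difference", {
  d <- trial_df(z = c(1, 1, 0, 0), x = c(1, 1, 1, 1),
                s = c(3, 5, 1, 1), t = rnorm(4))
  o <- observed_surrogate_effect(d, "N", x = 1)
  expect_equal(o$o_s, 3)
  expect_equal(c(o$n1x, o$n0x), c(2, 2))
  dc <- trial_df(z = c(1, 0), s = c(7, 7), t = c(0, 0))
  expect_equal(observed_surrogate_effect(dc, "N")$o_s, 0)
  expect_error(observed_surrogate_effect(d, "N", x = 0), "x=0.*empty arm")
  # with parameters, the inflated variance d~aa is attached
  p1 <- sp_sim_params("S1")
  o2 <- observed_surrogate_effect(d, "N", x = 1, params = p1)
  expect_equal(o2$d_aa_tilde, 1 + 1 * (1 / 2 + 1 / 2))
})

test_that("observed surrogate effect converges to the true effect", {
  set.seed(21)
  d <- sp_design("S1", n_trials = 1, n_per_trial = 2e4, n_replicates = 2)
  dat <- simulate_meta(d, seed = 21)
  g <- attr(dat, "random_effects")[1, ]
  o <- observed_surrogate_effect(dat, 1, x = 0)
  truth <- 2 + g["bS"]   # beta_S + bS (delta_S x vanishes at x = 0)
  se <- sqrt(2 * (1 / o$n1x + 1 / o$n0x))   # generous: dss + sigma_ss = 2
  expect_lt(abs(o$o_s - truth), 4 * se)
})

test_that("conditional harm probability matches its closed form and an MC oracle", {
  p1 <- sp_sim_params("S1")
  j0 <- joint_effect_distribution(p1, 0)
  daa_t <- j0$cov[1, 1] + p1$sigma[1, 1] * (1 / 25 + 1 / 25)
  v <- j0$cov[2, 2] - j0$cov[1, 2]^2 / daa_t
  # conditioning at the mean leaves no shift
  expect_equal(prob_harm_given_s(p1, 0, s = j0$mean[1], n1x = 25, n0x = 25),
               unname(pnorm(-j0$mean[2] / sqrt(v))))
  # with dab* = 0 the observed surrogate effect carries no information
  pu <- sp_params("S1", fixed = p1$fixed, D = diag(4), sigma = p1$sigma)
  expect_equal(prob_harm_given_s(pu, 0, s = -3, n1x = 10, n0x = 10),
               prob_harm_given_s(pu, 0, s = 3, n1x = 10, n0x = 10))
  # Monte-Carlo conditional-density oracle at s = 0
  set.seed(13)
  n <- 1e6
  OS_DT <- mvtnorm::rmvnorm(n, mean = j0$mean,
                            sigma = matrix(c(daa_t, j0$cov[1, 2],
                                             j0$cov[1, 2], j0$cov[2, 2]), 2))
  sel <- abs(OS_DT[, 1] - 0) < 0.01
  p_mc <- mean(OS_DT[sel, 2] < 0)
  p_an <- prob_harm_given_s(p1, 0, s = 0, n1x = 25, n0x = 25)
  expect_lt(abs(p_an - p_mc), 3 * binom_se(p_mc, sum(sel)))
})

test_that("s-threshold: root-finder, closed form and defining property agree", {
  p1 <- sp_sim_params("S1")
  for (x in c(0, 1)) {
    st <- s_threshold(p1, x, alpha = 0.05, n1x = 25, n0x = 25)
    expect_lt(abs(st$s - st$s_closed_form), 1e-8)
    expect_lt(abs(st$prob_at_s(st$s) - 0.05), 1e-8)
  }
  p2 <- sp_sim_params("S2")
  st2 <- s_threshold(p2, 1, alpha = 0.05, n1x = 25, n0x = 25)
  expect_lt(abs(st2$s - st2$s_closed_form), 1e-8)
  # monotonicity: nonincreasing in alpha and in the true-endpoint mean
  alphas <- c(0.01, 0.05, 0.1, 0.2)
  ss <- vapply(alphas, function(a)
    s_threshold(p1, 0, a, n1x = 25, n0x = 25)$s, 0)
  expect_true(all(diff(ss) <= 1e-10))
  fx <- p1$fixed
  s_by_bt <- vapply(c(0.5, 1, 2), function(bt) {
    fx["beta_T"] <- bt
    s_threshold(sp_params("S1", fx, p1$D, p1$sigma), 0, 0.05, 25, 25)$s
  }, 0)
  expect_true(all(diff(s_by_bt) <= 1e-10))
  # a nonpositive surrogate-outcome association has no defined threshold
  pu <- sp_params("S1", fixed = p1$fixed, D = diag(4), sigma = p1$sigma)
  expect_error(s_threshold(pu, 0, 0.05, 25, 25), "dab")
})

test_that("marginal measure is the weighted average over covariate levels", {
  expect_equal(marginal_psi(0.8), 0.8)
  expect_equal(marginal_psi(c(0.8, 0.9)), 0.85)
  expect_error(marginal_psi(numeric(0)), "empty")
  expect_error(marginal_psi(c(.5, .5), c(.9, .3)), "sum to 1")
  # sample-average approximation vs exact integral over x ~ U(0, 1)
  p1 <- toy_params_s1()
  f <- function(x) vapply(x, function(xi)
    psi_sp13(joint_effect_distribution(p1, xi)), 0)
  exact <- stats::integrate(f, 0, 1)$value
  set.seed(9)
  xs <- stats::runif(2000)
  approx <- marginal_psi(f(xs))
  expect_lt(abs(approx - exact), 3 * sd(f(xs)) / sqrt(2000))
})
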