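# Global-local hierarchies: inverse-gamma mixture machinery, each Gibbs
# conditional against the grid oracle, and the Metropolis-Hastings step for
# the half-t degrees of freedom.

test_that("chained IG mixtures reconstruct the half-Cauchy", {
  set.seed(101)
  ndraw <- 1e5
  for (A in c(1, 1 / 250)) {
    aux <- rinvgamma(ndraw, 0.5, 1 / A^2)
    x <- sqrt(rinvgamma(ndraw, 0.5, 1 / aux))
    expect_lt(ks_dist(x, function(q) phalf_cauchy(q, A)), 0.01)
  }
})

test_that("bayesU local conditionals match the grid oracle", {
  st <- tiny_state("bayesU", seed = 41)
  k <- 2L
  # lambda_k^2 | beta_k, tau2, nu_k: factors N(beta; 0, l2 tau2) x IG prior
  lk <- function(l2)
    dnorm(st$beta[k], 0, sqrt(l2 * st$tau2), log = TRUE) +
      dinvgamma(l2, 0.5, 1 / st$nu_aux[k], log = TRUE)
  expect_lt(grid_gap_ig(lk, 1, 1 / st$nu_aux[k] +
                          st$beta[k]^2 / (2 * st$tau2)), 1e-3)
  # nu_k | lambda_k^2
  lk2 <- function(nu)
    dinvgamma(st$lambda2[k], 0.5, 1 / nu, log = TRUE) +
      dinvgamma(nu, 0.5, 1, log = TRUE)
  expect_lt(grid_gap_ig(lk2, 1, 1 + 1 / st$lambda2[k]), 1e-3)

  # prior-composed local scale is half-Cauchy(0, 1)
  set.seed(42)
  nu <- rinvgamma(1e5, 0.5, 1)
  lam <- sqrt(rinvgamma(1e5, 0.5, 1 / nu))
  expect_lt(ks_dist(lam, phalf_cauchy), 0.01)
})

test_that("bayesU global conditional: flat prior on tau, grid oracle", {
  st <- tiny_state("bayesU", m = 5, seed = 43)
  s <- sum(st$beta^2 / st$lambda2)
  m <- length(st$beta)
  # factors: prod_k N(beta_k; 0, lambda_k^2 tau2) x transform (tau2)^(-1/2)
  lk <- function(t2) vapply(t2, function(tt)
    sum(dnorm(st$beta, 0, sqrt(st$lambda2 * tt), log = TRUE)) -
      0.5 * log(tt), numeric(1))
  expect_lt(grid_gap_ig(lk, (m - 1) / 2, s / 2), 1e-3)

  # doubling the effects quadruples the conditional rate S/2
  st2 <- st; st2$beta <- 2 * st$beta
  expect_equal(sum(st2$beta^2 / st2$lambda2), 4 * s)

  st1 <- st; st1$beta <- st1$beta[1]; st1$lambda2 <- st1$lambda2[1]
  expect_error(update_global_bayesU(st1), "improper")
})

test_that("bayesHP local conditionals match the grid oracle", {
  st <- tiny_state("bayesHP", seed = 44)
  k <- 1L
  lk_l2 <- function(l2)
    dnorm(st$beta[k], 0, sqrt(l2 * st$tau2), log = TRUE) +
      dinvgamma(l2, 0.5, 1 / st$theta[k], log = TRUE)
  expect_lt(grid_gap_ig(lk_l2, 1, 1 / st$theta[k] +
                          st$beta[k]^2 / (2 * st$tau2)), 1e-3)
  lk_th <- function(th)
    dinvgamma(st$lambda2[k], 0.5, 1 / th, log = TRUE) +
      dinvgamma(th, 0.5, 1 / st$eta2[k], log = TRUE)
  expect_lt(grid_gap_ig(lk_th, 1, 1 / st$eta2[k] + 1 / st$lambda2[k]), 1e-3)
  lk_e2 <- function(e2)
    dinvgamma(st$theta[k], 0.5, 1 / e2, log = TRUE) +
      dinvgamma(e2, 0.5, 1 / st$nu_aux[k], log = TRUE)
  expect_lt(grid_gap_ig(lk_e2, 1, 1 / st$nu_aux[k] + 1 / st$theta[k]), 1e-3)
  lk_nu <- function(nu)
    dinvgamma(st$eta2[k], 0.5, 1 / nu, log = TRUE) +
      dinvgamma(nu, 0.5, 1, log = TRUE)
  expect_lt(grid_gap_ig(lk_nu, 1, 1 + 1 / st$eta2[k]), 1e-3)
})

test_that("composed Horseshoe+ local prior equals the two half-Cauchy layers", {
  set.seed(45)
  ndraw <- 1e5
  # path 1: the chained IG hierarchy
  nu <- rinvgamma(ndraw, 0.5, 1)
  e2 <- rinvgamma(ndraw, 0.5, 1 / nu)
  th <- rinvgamma(ndraw, 0.5, 1 / e2)
  lam_mix <- sqrt(rinvgamma(ndraw, 0.5, 1 / th))
  # path 2: lambda ~ C+(0, eta), eta ~ C+(0, 1) sampled directly
  eta <- rhalf_cauchy(ndraw, 1)
  lam_dir <- rhalf_cauchy(ndraw, eta)
  q <- quantile(lam_dir, seq(0.02, 0.98, by = 0.02))
  ecdf_mix <- ecdf(lam_mix)
  ecdf_dir <- ecdf(lam_dir)
  expect_lt(max(abs(ecdf_mix(q) - ecdf_dir(q))), 0.01)
})

test_that("bayesHP/bayesHE global conditionals match mixture and oracle", {
  # prior-composed tau is C+(0, 1/N)
  set.seed(46)
  N <- 120
  xi <- rinvgamma(1e5, 0.5, N^2)
  tau <- sqrt(rinvgamma(1e5, 0.5, 1 / xi))
  expect_lt(ks_dist(tau, function(q) phalf_cauchy(q, 1 / N)), 0.01)

  st <- tiny_state("bayesHP", m = 4, seed = 47)
  s <- sum(st$beta^2 / st$lambda2)
  m <- length(st$beta)
  lk_t2 <- function(t2) vapply(t2, function(tt)
    sum(dnorm(st$beta, 0, sqrt(st$lambda2 * tt), log = TRUE)) +
      dinvgamma(tt, 0.5, 1 / st$xi, log = TRUE), numeric(1))
  expect_lt(grid_gap_ig(lk_t2, (m + 1) / 2, 1 / st$xi + s / 2), 1e-3)

  for (N2 in c(8, 16)) {  # the prior rate enters as N^2
    stN <- st; stN$data$N <- N2
    lk_xi <- function(xi)
      dinvgamma(st$tau2, 0.5, 1 / xi, log = TRUE) +
        dinvgamma(xi, 0.5, N2^2, log = TRUE)
    expect_lt(grid_gap_ig(lk_xi, 1, N2^2 + 1 / st$tau2), 1e-3)
  }
})

test_that("bayesHE local conditionals match the grid oracle at several df", {
  for (u in c(1, 4, 30)) {
    st <- tiny_state("bayesHE", seed = 48)
    st$upsilon <- u
    k <- 3L
    lk_l2 <- function(l2)
      dnorm(st$beta[k], 0, sqrt(l2 * st$tau2), log = TRUE) +
        dinvgamma(l2, u / 2, u / st$theta[k], log = TRUE)
    expect_lt(grid_gap_ig(lk_l2, u / 2 + 0.5,
                          u / st$theta[k] + st$beta[k]^2 / (2 * st$tau2)),
              1e-3)
    lk_th <- function(th) vapply(th, function(t1)
      dinvgamma(st$lambda2[k], u / 2, u / t1, log = TRUE) +
        dinvgamma(t1, 0.5, 1, log = TRUE), numeric(1))
    expect_lt(grid_gap_ig(lk_th, u / 2 + 0.5, 1 + u / st$lambda2[k]), 1e-3)
  }
})

test_that("bayesHE at df = 1 reduces to the Horseshoe local prior", {
  set.seed(49)
  ndraw <- 1e5
  th <- rinvgamma(ndraw, 0.5, 1)
  lam_he <- sqrt(rinvgamma(ndraw, 0.5, 1 / th))
  expect_lt(ks_dist(lam_he, phalf_cauchy), 0.015)

  # large df with theta = 1: lambda^2 concentrates, spread decreasing in df
  iqr <- vapply(c(5, 20, 80), function(u) {
    set.seed(50)
    diff(quantile(rinvgamma(2e4, u / 2, u), c(0.25, 0.75)))
  }, numeric(1))
  expect_true(all(diff(iqr) < 0))
})

test_that("log_conditional_df matches its displayed kernel and edge cases", {
  # m = 0 reduces to the Gamma(a, b) log-kernel up to a constant
  u <- c(0.5, 1, 3, 7)
  l0 <- log_conditional_df(u, numeric(0), numeric(0), a = 4, b = 1, m = 0)
  expect_equal(l0 - l0[1],
               (4 - 1) * log(u) - u - ((4 - 1) * log(u[1]) - u[1]))

  # m = 1 with unit scales: log-sum term 0, reciprocal term 1
  u1 <- 2.5
  expect_equal(log_conditional_df(u1, 1, 1, a = 4, b = 1),
               (u1 / 2 + 3) * log(u1) - lgamma(u1 / 2) - u1 * (0 + 1 + 1))
  expect_error(log_conditional_df(-1, 1, 1, 4, 1), "positive")
  expect_error(log_conditional_df(2, c(1, -1), c(1, 1), 4, 1), "positive")
})

test_that("MH on log-df recovers the prior and the quadrature posterior", {
  # degenerate proposal: acceptance ~ 1, chain nearly constant
  st <- tiny_state("bayesHE", m = 5, seed = 51)
  set.seed(52)
  acc <- replicate(200, sample_df_mh(st, 4, 1, 1e-8)$accepted)
  expect_gt(mean(acc), 0.95)

  # m = 0: the MH marginal is the Gamma(a, b) prior, mean a/b
  run_mh <- function(st, a, b, m, n_iter, step = 0.8) {
    out <- numeric(n_iter)
    for (i in seq_len(n_iter)) {
      r <- sample_df_mh(st, a, b, step, m = m)
      st$upsilon <- r$new_upsilon
      out[i] <- st$upsilon
    }
    out
  }
  set.seed(53)
  st0 <- st
  ch <- run_mh(st0, a = 4, b = 1, m = 0, n_iter = 60000)
  expect_lt(abs(mean(ch) - 4), 3 * batch_se(ch))

  # m = 50 frozen state simulated at df 6: MH mean vs quadrature mean
  set.seed(54)
  u_true <- 6
  theta <- rinvgamma(50, 0.5, 1)
  lambda2 <- rinvgamma(50, u_true / 2, u_true / theta)
  stf <- st; stf$theta <- theta; stf$lambda2 <- lambda2; stf$upsilon <- 5
  ch2 <- run_mh(stf, a = 4, b = 1, m = 50, n_iter = 60000, step = 0.35)
  qmean <- quadrature_df_mean(theta, lambda2, a = 4, b = 1)
  expect_lt(abs(mean(ch2) - qmean), 3 * batch_se(ch2))
})

test_that("MH flow between two df bins balances on a frozen target", {
  set.seed(55)
  st <- tiny_state("bayesHE", m = 5, seed = 55)
  n_iter <- 40000
  ch <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    r <- sample_df_mh(st, 4, 1, 0.8)
    st$upsilon <- r$new_upsilon
    ch[i] <- st$upsilon
  }
  qs <- quantile(ch, c(0.25, 0.75))
  in_a <- ch[-n_iter] < qs[1] & ch[-1] > qs[2]   # direct low -> high jumps
  in_b <- ch[-n_iter] > qs[2] & ch[-1] < qs[1]   # direct high -> low jumps
  flow_ab <- sum(in_a); flow_ba <- sum(in_b)
  expect_gt(flow_ab + flow_ba, 100)  # enough direct jumps to test balance
  expect_lt(abs(flow_ab - flow_ba), 4 * sqrt(flow_ab + flow_ba))
})

test_that("conditional |beta_k| mean is non-decreasing in lambda2 * tau2", {
  st <- tiny_state("bayesU", seed = 56)
  k <- 1L
  folded_mean <- function(mu, sd)
    sd * sqrt(2 / pi) * exp(-mu^2 / (2 * sd^2)) + mu * (1 - 2 * pnorm(-mu / sd))
  pv <- 10^seq(-6, 3, length.out = 30)
  em <- vapply(pv, function(v) {
    cm <- bayesgl:::conditional_marker_effect(st, k, v)
    folded_mean(cm$mean, sqrt(cm$var))
  }, numeric(1))
  expect_true(all(diff(em) > -1e-12))
})
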