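# Shared Gibbs engine: initialisation, the mu / beta_k / sigma2_e
# conditionals, chain control, and the DGV / additive-variance helpers.

test_that("init_state centres correctly and seeds every latent quantity", {
  g <- genotype_matrix(matrix(c(0, 1, 2, 2, 1, 0), nrow = 3),
                       c("a", "b", "c"), c("s1", "s2"))
  ph <- phenotype_table(c("a", "b", "c"), c(1, 2, 3))
  st <- init_state(g, ph, model_spec("bayesU"), chain_config(fast = TRUE))
  expect_equal(st$mu, 2)
  expect_equal(st$resid, c(-1, 0, 1))
  expect_equal(st$beta, c(0, 0))
  expect_equal(st$lambda2, c(1, 1))
  expect_equal(unname(colMeans(st$data$X)), c(0, 0))

  # bayesHE initialises the df at its prior mean a/b
  st2 <- init_state(g, ph, model_spec("bayesHE", a = 4, b = 1),
                    chain_config(fast = TRUE))
  expect_equal(st2$upsilon, 4)

  ph_bad <- phenotype_table(c("x", "y", "z"), c(1, 2, 3))
  expect_error(init_state(g, ph_bad, model_spec("bayesU"),
                          chain_config(fast = TRUE)), "no individuals shared")
})

test_that("intercept conditional matches its closed form", {
  st <- tiny_state("bayesU", n = 5, m = 2, seed = 21)
  cm <- bayesgl:::conditional_intercept(st)
  # homogeneous weights: conditional variance is sigma2_e / n
  expect_equal(cm$var, st$sigma2_e / st$data$n)
  r <- st$resid + st$mu
  expect_equal(cm$mean, sum(st$data$w * r) / sum(st$data$w))

  # moment check: empirical mean/var of draws against the closed form
  set.seed(1)
  draws <- replicate(1e5, update_intercept(st)$mu)
  expect_lt(abs(mean(draws) - cm$mean), 3 * sqrt(cm$var / 1e5))
  expect_lt(abs(var(draws) - cm$var), 4 * cm$var * sqrt(2 / 1e5))

  # heterogeneous weights: grid oracle on the log-kernel built from factors
  std <- tiny_state("bayesU", n = 6, m = 2, seed = 22)
  std$data$w <- c(1, 2, 0.5, 1, 4, 0.25)
  cmw <- bayesgl:::conditional_intercept(std)
  rfull <- std$resid + std$mu
  lk <- function(mu) vapply(mu, function(m0)
    sum(dnorm(rfull, m0, sqrt(std$sigma2_e / std$data$w), log = TRUE)),
    numeric(1))
  expect_lt(grid_gap_norm(lk, cmw$mean, sqrt(cmw$var)), 1e-3)
})

test_that("marker-effect conditional matches the grid oracle and limits", {
  st <- tiny_state("bayesU", n = 8, m = 2, seed = 23)
  st$data$w <- exp(rnorm(8, 0, 0.4))
  st$data$xtwx <- colSums(st$data$X^2 * st$data$w)
  k <- 1L
  pv <- 0.35
  cm <- bayesgl:::conditional_marker_effect(st, k, pv)
  xk <- st$data$X[, k]
  r_k <- st$resid + xk * st$beta[k]
  lk <- function(b) vapply(b, function(bb)
    sum(dnorm(r_k, xk * bb, sqrt(st$sigma2_e / st$data$w), log = TRUE)) +
      dnorm(bb, 0, sqrt(pv), log = TRUE), numeric(1))
  expect_lt(grid_gap_norm(lk, cm$mean, sqrt(cm$var)), 1e-3)

  # flat-prior limit: conditional mean -> weighted least squares estimate
  cm_flat <- bayesgl:::conditional_marker_effect(st, k, 1e12)
  wls <- sum(st$data$w * xk * r_k) / sum(st$data$w * xk^2)
  expect_equal(cm_flat$mean, wls, tolerance = 1e-6)

  # total-shrinkage limit
  cm0 <- bayesgl:::conditional_marker_effect(st, k, 1e-14)
  expect_lt(abs(cm0$mean), 1e-10)
  expect_error(update_marker_effect(st, k, -1), "positive")
})

test_that("residual-variance conditional has the right moments and scaling", {
  st <- tiny_state("bayesU", n = 50, m = 2, seed = 24)
  cp <- bayesgl:::conditional_residual_variance(st)
  expect_equal(cp$shape, 25)  # Jeffreys prior: n/2
  set.seed(2)
  draws <- rinvgamma(1e5, cp$shape, cp$rate)
  an_mean <- cp$rate / (cp$shape - 1)
  an_sd <- an_mean / sqrt(cp$shape - 2)
  expect_lt(abs(mean(draws) - an_mean), 3 * an_sd / sqrt(1e5))

  # doubling all d_ii halves the weighted sum of squares (w = 1/d)
  st2 <- st; st2$data$w <- st$data$w / 2
  expect_equal(bayesgl:::conditional_residual_variance(st2)$rate,
               cp$rate / 2)
  expect_true(all(replicate(50, update_residual_variance(st)$sigma2_e) > 0))
})

test_that("chain control: saved-draw count, determinism, divergent configs", {
  cfg <- chain_config()
  expect_equal((cfg$n_iter - cfg$burn_in) %/% cfg$thin, 600L)
  expect_error(chain_config(n_iter = 1000, burn_in = 1000), "smaller")
  expect_error(chain_config(n_iter = 1000, burn_in = 990, thin = 10),
               "fewer than 10")

  td <- tiny_data(n = 30, m = 10, seed = 5)
  cc <- chain_config(n_iter = 300, burn_in = 100, thin = 10, seed = 99)
  f1 <- run_chain(td$g, td$ph, model_spec("bayesHP"), cc)
  f2 <- run_chain(td$g, td$ph, model_spec("bayesHP"), cc)
  expect_identical(f1$beta_mean, f2$beta_mean)
  expect_identical(f1$vg_trace, f2$vg_trace)
  expect_equal(f1$n_saved, 20L)
})

test_that("compiled marker sweep draws identically to the R update path", {
  for (fam in c("bayesU", "bayesB")) {
    st <- tiny_state(fam, n = 12, m = 6, seed = 31)
    d <- st$data
    if (fam == "bayesB") {
      set.seed(77)
      cpp <- bayesb_sweep_cpp(d$X, d$w, d$xtwx, st$resid, st$beta, st$delta,
                              st$sigma2_beta_k, st$sigma2_e, st$spec$pi)
      set.seed(77)
      str <- st
      for (k in seq_len(d$m)) str <- update_bayesB_indicator(str, k)
      expect_equal(cpp$beta, str$beta, tolerance = 1e-13)
      expect_equal(cpp$delta, str$delta)
      expect_equal(cpp$resid, str$resid, tolerance = 1e-13)
    } else {
      pv <- st$lambda2 * st$tau2
      set.seed(77)
      cpp <- marker_sweep_cpp(d$X, d$w, d$xtwx, st$resid, st$beta, pv,
                              st$sigma2_e)
      set.seed(77)
      str <- st
      for (k in seq_len(d$m)) str <- update_marker_effect(str, k, pv[k])
      expect_equal(cpp$beta, str$beta, tolerance = 1e-13)
      expect_equal(cpp$resid, str$resid, tolerance = 1e-13)
    }
  }
})

test_that("incremental residuals stay consistent over a long chain", {
  td <- tiny_data(n = 25, m = 15, seed = 6)
  for (fam in c("bayesHE", "bayesB")) {
    set.seed(8)
    st <- init_state(td$g, td$ph, model_spec(fam, s2_beta = 0.05),
                     chain_config(fast = TRUE))
    for (i in 1:2000) st <- bayesgl:::gibbs_sweep_r(st)
    fresh <- st$data$y - st$mu - drop(st$data$X %*% st$beta)
    expect_lt(max(abs(fresh - st$resid)), 1e-8)
  }
})

test_that("genomic values are linear in effects and exclude the intercept", {
  g <- genotype_matrix(matrix(c(0, 1, 2), 3, 1), c("a", "b", "c"), "s1")
  expect_equal(unname(genomic_values(g, 0.5)), c(0, 0.5, 1.0))
  expect_equal(unname(genomic_values(g, 0)), c(0, 0, 0))
  expect_error(genomic_values(g, c(1, 2)), "mismatch")

  set.seed(10)
  g2 <- genotype_matrix(matrix(sample(0:2, 40, TRUE), 8, 5))
  b <- rnorm(5)
  perm <- sample(5)
  g2p <- genotype_matrix(g2$codes[, perm], g2$individual_ids,
                         g2$marker_ids[perm])
  expect_equal(genomic_values(g2p, b[perm]), genomic_values(g2, b))
})

test_that("additive variance uses the n-1 denominator and scales in beta^2", {
  g <- genotype_matrix(matrix(c(0, 2), 2, 1))
  expect_equal(additive_variance(g, 1), 2)
  expect_equal(additive_variance(g, 0), 0)
  set.seed(11)
  g2 <- genotype_matrix(matrix(sample(0:2, 60, TRUE), 12, 5))
  b <- rnorm(5)
  expect_equal(additive_variance(g2, 3 * b), 9 * additive_variance(g2, b))
})
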