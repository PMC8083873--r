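# Joint-distribution (Geweke-style) validation machinery.
#
# Two samplers for the joint p(theta, y): "marginal-conditional" (draw theta
# from the prior, then y | theta; independent replicates) and
# "successive-conditional" (alternate a Gibbs sweep for theta | y with a
# fresh draw of y | theta). If every Gibbs conditional is correct both
# target the same joint, so the moments of any statistic must agree.
#
# Proper priors are required to draw theta: the test spec uses mu ~ N(0, 1)
# and sigma2_e ~ IG(6, 5). For bayesU the flat tau prior is improper, so
# tau2 is held fixed at 0.5 (a valid Gibbs sampler for that submodel) and
# only mu/sigma2_e moments are compared; HP and HE have proper tau priors
# through the xi mixture and tau2 moments are compared as well.

geweke_spec <- function(family) {
  model_spec(family,
             pi = if (family == "bayesB") 0.6 else 0.95,
             a = 4, b = 1, df_ab = 4.2, s2_beta = 0.5, adapt_mh = FALSE,
             mh_step = 0.8,
             prior_mu = c(0, 1), prior_sigma2e = c(6, 5))
}

# draw all latent parameters from their priors (theta | nothing)
geweke_prior_draw <- function(st) {
  fam <- st$spec$family
  m <- st$data$m
  N <- st$data$N
  st$mu <- rnorm(1, st$spec$prior_mu[1], sqrt(st$spec$prior_mu[2]))
  st$sigma2_e <- rinvgamma(1, st$spec$prior_sigma2e[1],
                           st$spec$prior_sigma2e[2])
  if (fam %in% c("bayesHP", "bayesHE")) {
    st$xi <- rinvgamma(1, 0.5, N^2)
    st$tau2 <- rinvgamma(1, 0.5, 1 / st$xi)
  }
  if (fam == "bayesU") {
    st$nu_aux <- rinvgamma(m, 0.5, 1)
    st$lambda2 <- rinvgamma(m, 0.5, 1 / st$nu_aux)
  } else if (fam == "bayesHP") {
    st$nu_aux <- rinvgamma(m, 0.5, 1)
    st$eta2 <- rinvgamma(m, 0.5, 1 / st$nu_aux)
    st$theta <- rinvgamma(m, 0.5, 1 / st$eta2)
    st$lambda2 <- rinvgamma(m, 0.5, 1 / st$theta)
  } else if (fam == "bayesHE") {
    repeat {
      st$upsilon <- rgamma(1, st$spec$a, rate = st$spec$b)
      if (st$upsilon >= 0.05 && st$upsilon <= 200) break
    }
    st$theta <- rinvgamma(m, 0.5, 1)
    st$lambda2 <- rinvgamma(m, st$upsilon / 2, st$upsilon / st$theta)
  } else if (fam %in% c("bayesA", "bayesB")) {
    df <- st$spec$df_ab
    st$sigma2_beta_k <- rinvgamma(m, df / 2, df * st$spec$s2_beta / 2)
  }
  # match the sampler's clamped local-variance support
  st$lambda2 <- pmin(pmax(st$lambda2, 1e-12), 1e12)
  if (fam == "bayesB") {
    st$delta <- rbinom(m, 1, 1 - st$spec$pi)
    st$beta <- st$delta * rnorm(m, 0, sqrt(st$sigma2_beta_k))
  } else if (fam %in% c("bayesA")) {
    st$beta <- rnorm(m, 0, sqrt(st$sigma2_beta_k))
  } else {
    st$beta <- rnorm(m, 0, sqrt(pmin(pmax(st$lambda2, 1e-12), 1e12) *
                                  st$tau2))
  }
  st
}

# regenerate y | theta and restore the residual identity
geweke_data_draw <- function(st) {
  d <- st$data
  xb <- drop(d$X %*% st$beta)
  y <- st$mu + xb + rnorm(d$n, 0, sqrt(d$d * st$sigma2_e))
  st$data$y <- y
  st$resid <- y - st$mu - xb
  st
}

# one Gibbs sweep theta | y via the granular update functions
geweke_gibbs_sweep <- function(st) {
  fam <- st$spec$family
  st <- update_intercept(st)
  if (fam == "bayesB") {
    for (k in seq_len(st$data$m)) st <- update_bayesB_indicator(st, k)
    st <- update_bayesA_variance(st)
  } else if (fam == "bayesA") {
    for (k in seq_len(st$data$m))
      st <- update_marker_effect(st, k, st$sigma2_beta_k[k])
    st <- update_bayesA_variance(st)
  } else {
    pv <- pmin(pmax(st$lambda2, 1e-12), 1e12) * st$tau2
    for (k in seq_len(st$data$m))
      st <- update_marker_effect(st, k, pv[k])
    if (fam == "bayesU") {
      st <- update_locals_bayesU(st)          # tau2 held fixed (flat prior)
    } else if (fam == "bayesHP") {
      st <- update_global_bayesHP(update_locals_bayesHP(st))
    } else if (fam == "bayesHE") {
      st <- update_global_bayesHP(update_locals_bayesHE(st))
      res <- sample_df_mh(st, st$spec$a, st$spec$b, st$spec$mh_step)
      st$upsilon <- res$new_upsilon
    }
  }
  update_residual_variance(st)
}

# tau ~ C+(0, 1/N) has no finite moments, so tau2 is compared on the log
# scale where the half-Cauchy mixture has finite first and second moments
geweke_stats <- function(st, with_tau = FALSE) {
  s <- c(mu = st$mu, mu2 = st$mu^2,
         se2 = st$sigma2_e, se2sq = st$sigma2_e^2)
  if (with_tau) s <- c(s, ltau2 = log(st$tau2), ltau2sq = log(st$tau2)^2)
  s
}

# Returns the largest |z| over the compared moments. The successive-
# conditional side runs many independent chains, each initialised at an
# exact prior draw (i.e. already in stationarity), so chain means are
# independent unbiased replicates and their spread is a valid standard
# error even when the within-chain autocorrelation is long (the global
# scale of the horseshoe hierarchies mixes slowly at small m).
geweke_zmax <- function(family, n = 10, m = 5, n_marg = 4000L,
                        n_chain = 150L, chain_len = 400L, seed = 402) {
  set.seed(seed)
  td <- tiny_data(n, m, seed = seed)
  st0 <- init_state(td$g, td$ph, geweke_spec(family),
                    chain_config(fast = TRUE, seed = seed))
  if (family == "bayesU") st0$tau2 <- 0.5
  with_tau <- family %in% c("bayesHP", "bayesHE")
  # marginal-conditional: independent prior x data draws
  mc <- matrix(NA_real_, n_marg, length(geweke_stats(st0, with_tau)))
  for (i in seq_len(n_marg)) {
    st <- geweke_data_draw(geweke_prior_draw(st0))
    mc[i, ] <- geweke_stats(st, with_tau)
  }
  # successive-conditional: Gibbs sweeps interleaved with data regeneration
  cmeans <- matrix(NA_real_, n_chain, ncol(mc))
  for (cc in seq_len(n_chain)) {
    st <- geweke_data_draw(geweke_prior_draw(st0))
    acc <- numeric(ncol(mc))
    for (i in seq_len(chain_len)) {
      st <- geweke_gibbs_sweep(st)
      st <- geweke_data_draw(st)
      acc <- acc + geweke_stats(st, with_tau)
    }
    cmeans[cc, ] <- acc / chain_len
  }
  z <- vapply(seq_len(ncol(mc)), function(j) {
    se1 <- sd(mc[, j]) / sqrt(nrow(mc))
    se2 <- sd(cmeans[, j]) / sqrt(n_chain)
    (mean(mc[, j]) - mean(cmeans[, j])) / sqrt(se1^2 + se2^2)
  }, numeric(1))
  max(abs(z))
}
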