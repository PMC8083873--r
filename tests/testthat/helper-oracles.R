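# Shared oracles and fixtures.
#
# The grid oracles integrate the *hierarchy factors* numerically and compare
# the resulting CDF with the closed-form conditional the sampler draws from;
# they are independent of the shape/rate algebra under test.

# sup gap between the numerically normalised CDF of exp(log_kernel) and the
# analytic inverse-gamma CDF, on a log-spaced grid covering the IG mass
grid_gap_ig <- function(log_kernel, shape, rate, n_grid = 40001L) {
  lo <- qinvgamma(1e-7, shape, rate)
  hi <- qinvgamma(1 - 1e-7, shape, rate)
  x <- exp(seq(log(lo), log(hi), length.out = n_grid))
  lk <- log_kernel(x)
  f <- exp(lk - max(lk))
  dx <- diff(x)
  seg <- dx * (f[-1] + f[-length(f)]) / 2
  cdf <- c(0, cumsum(seg))
  cdf <- cdf / cdf[length(cdf)]
  max(abs(cdf - pinvgamma(x, shape, rate)))
}

# same, against a normal CDF (for the beta_k and mu conditionals)
grid_gap_norm <- function(log_kernel, mean, sd, n_grid = 40001L) {
  x <- seq(mean - 7 * sd, mean + 7 * sd, length.out = n_grid)
  lk <- log_kernel(x)
  f <- exp(lk - max(lk))
  dx <- x[2] - x[1]
  cdf <- c(0, cumsum(dx * (f[-1] + f[-length(f)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  max(abs(cdf - pnorm(x, mean, sd)))
}

# Kolmogorov-Smirnov distance of draws against a CDF function
ks_dist <- function(draws, cdf_fun) {
  x <- sort(draws)
  n <- length(x)
  Fx <- cdf_fun(x)
  max(pmax(abs(seq_len(n) / n - Fx), abs((seq_len(n) - 1) / n - Fx)))
}

# batch-means Monte-Carlo standard error for a (possibly autocorrelated)
# scalar chain
batch_se <- function(x, n_batch = 50L) {
  n <- length(x)
  bs <- n %/% n_batch
  bm <- colMeans(matrix(x[seq_len(bs * n_batch)], nrow = bs))
  sd(bm) / sqrt(n_batch)
}

# small aligned genotype/phenotype fixture with heterogeneous weights
tiny_data <- function(n = 8, m = 3, seed = 11, reliabilities = NULL) {
  set.seed(seed)
  codes <- matrix(sample(0:2, n * m, replace = TRUE, prob = c(.3, .4, .3)),
                  n, m)
  # guarantee polymorphism
  codes[1, ] <- 0; codes[2, ] <- 2
  g <- genotype_matrix(codes, paste0("i", 1:n), paste0("s", 1:m))
  y <- rnorm(n, 1, 1.5)
  ph <- phenotype_table(paste0("i", 1:n), y, reliabilities)
  list(g = g, ph = ph)
}

# sampler state on a tiny fixture, with latent scales perturbed away from
# their initial values so conditionals are exercised at generic points
tiny_state <- function(family = "bayesU", n = 8, m = 3, seed = 11,
                       spec = NULL, ...) {
  td <- tiny_data(n, m, seed)
  if (is.null(spec)) spec <- model_spec(family, ...)
  st <- init_state(td$g, td$ph, spec, chain_config(fast = TRUE, seed = seed))
  set.seed(seed + 1)
  mm <- length(st$beta)
  st$beta <- rnorm(mm, 0, 0.6)
  st$resid <- st$data$y - st$mu - drop(st$data$X %*% st$beta)
  st$lambda2 <- exp(rnorm(mm, 0, 0.5))
  st$theta <- exp(rnorm(mm, 0, 0.5))
  st$eta2 <- exp(rnorm(mm, 0, 0.5))
  st$nu_aux <- exp(rnorm(mm, 0, 0.5))
  st$tau2 <- 0.7
  st$xi <- 1.3
  st$sigma2_beta_k <- exp(rnorm(mm, log(0.05), 0.3))
  st
}

# posterior mean of the half-t df by direct quadrature of the conditional
quadrature_df_mean <- function(theta, lambda2, a, b, m = length(lambda2)) {
  u <- exp(seq(log(0.05), log(200), length.out = 20001L))
  lk <- log_conditional_df(u, theta, lambda2, a, b, m)
  f <- exp(lk - max(lk))
  du <- diff(u)
  w <- c(du / 2, 0) + c(0, du / 2)   # trapezoid weights
  sum(u * f * w) / sum(f * w)
}
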