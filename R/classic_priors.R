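# BayesA / BayesB conditional updates.
#
# The scaled-t prior of BayesA is represented through per-marker variances
#   beta_k | sigma2_beta_k ~ N(0, sigma2_beta_k),
#   sigma2_beta_k ~ scaled-inv-chi2(df, s2_beta) = IG(df/2, df * s2_beta / 2).
# BayesB multiplies a point mass at zero with probability pi; BayesA is the
# pi = 0 special case.

#' Per-marker variance update for BayesA / BayesB
#'
#' Draws each `sigma2_beta_k` from its scaled-inverse-chi-square full
#' conditional with `df_ab + 1` degrees of freedom, i.e.
#' `IG((df_ab + 1)/2, (df_ab * s2_beta + beta_k^2)/2)`. For bayesB markers
#' currently excluded (`delta_k = 0`, so `beta_k = 0`), this is the prior
#' with the df incremented at zero squared-effect contribution, which is
#' also the exact conditional in the collapsed formulation.
#'
#' @param state a `sampler_state` with family bayesA or bayesB.
#' @param k marker indices (default all, vectorised).
#' @return updated state.
#' @export
update_bayesA_variance <- function(state, k = seq_along(state$beta)) {
  df <- state$spec$df_ab
  s2 <- state$spec$s2_beta
  state$sigma2_beta_k[k] <-
    rinvgamma(length(k), (df + 1) / 2, (df * s2 + state$beta[k]^2) / 2)
  state
}

# log Bayes factor (marker in vs out) and conditional moments, with beta_k
# integrated out analytically against the current residuals
bayesB_inclusion <- function(state, k) {
  d <- state$data
  xk <- d$X[, k]
  r_k <- state$resid + xk * state$beta[k]
  c_k <- d$xtwx[k]
  v0 <- state$sigma2_beta_k[k]
  vpost <- 1 / (c_k / state$sigma2_e + 1 / v0)
  rhs <- sum(d$w * xk * r_k) / state$sigma2_e
  log_bf <- 0.5 * log(vpost / v0) + 0.5 * rhs^2 * vpost
  pi_ <- state$spec$pi
  # P(delta=1 | .) = (1-pi) BF / ((1-pi) BF + pi)
  p1 <- if (pi_ == 0) 1
        else if (pi_ == 1) 0
        else 1 / (1 + exp(log(pi_ / (1 - pi_)) - log_bf))
  list(p1 = p1, mean = vpost * rhs, var = vpost, log_bf = log_bf)
}

#' Indicator-and-effect update for BayesB
#'
#' Collapsed Gibbs update of the inclusion indicator `delta_k`: `beta_k` is
#' integrated out analytically, giving a Bernoulli conditional from the
#' likelihood ratio of the marker-in vs marker-out models on the current
#' residuals. If the marker is included, `beta_k` is then drawn from its
#' normal conditional; otherwise `beta_k` is set to zero and the residuals
#' restored.
#'
#' @param state a `sampler_state` with family bayesB.
#' @param k marker index.
#' @return updated state.
#' @export
update_bayesB_indicator <- function(state, k) {
  inc <- bayesB_inclusion(state, k)
  new_delta <- as.integer(runif(1) < inc$p1)
  new_b <- if (new_delta == 1L) rnorm(1, inc$mean, sqrt(inc$var)) else 0
  state$resid <- state$resid + state$data$X[, k] * (state$beta[k] - new_b)
  state$beta[k] <- new_b
  state$delta[k] <- new_delta
  state
}
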