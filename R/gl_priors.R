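# Conditional updates for the three global-local shrinkage hierarchies.
#
# All half-Cauchy and half-t scales are handled through the inverse-gamma
# mixture representation: if x^2 ~ IG(1/2, 1/a) and a ~ IG(1/2, 1/A^2)
# then x ~ C+(0, A). The hierarchies, in the package-wide IG(shape, rate)
# convention:
#
# BayesU (Horseshoe, flat global):
#   beta_k ~ N(0, lambda_k^2 tau^2), lambda_k^2 ~ IG(1/2, 1/nu_k),
#   nu_k ~ IG(1/2, 1), tau ~ flat.
# BayesHP (Horseshoe+):
#   lambda_k^2 ~ IG(1/2, 1/theta_k), theta_k ~ IG(1/2, 1/eta_k^2),
#   eta_k^2 ~ IG(1/2, 1/nu_k), nu_k ~ IG(1/2, 1),
#   tau^2 ~ IG(1/2, 1/xi), xi ~ IG(1/2, N^2)   [tau ~ C+(0, 1/N)].
# BayesHE (half-t local with unknown df):
#   lambda_k^2 ~ IG(upsilon/2, upsilon/theta_k), theta_k ~ IG(1/2, 1),
#   global as BayesHP, upsilon ~ Gamma(a, b) sampled by MH on log(upsilon).

# upsilon support; far outside plausible df, guards Gamma(upsilon/2) overflow
.UPSILON_MIN <- 0.05
.UPSILON_MAX <- 200

#' Local-scale updates for BayesU (Horseshoe)
#'
#' Draws `lambda_k^2` and its auxiliary `nu_k` from their inverse-gamma full
#' conditionals:
#' `lambda_k^2 | . ~ IG(1, 1/nu_k + beta_k^2/(2 tau^2))` and
#' `nu_k | . ~ IG(1, 1 + 1/lambda_k^2)`. With `beta_k = 0` the first reduces
#' to the prior given `nu_k` with its likelihood shape increment.
#'
#' @param state a `sampler_state` with family bayesU.
#' @param k marker indices to update (default: all markers, vectorised).
#' @return updated state.
#' @export
update_locals_bayesU <- function(state, k = seq_along(state$beta)) {
  b2 <- state$beta[k]^2
  state$lambda2[k] <- clamp_lambda2(
    rinvgamma(length(k), 1, 1 / state$nu_aux[k] + b2 / (2 * state$tau2)))
  state$nu_aux[k] <- rinvgamma(length(k), 1, 1 + 1 / state$lambda2[k])
  state
}

#' Global-scale update for BayesU (flat prior on tau)
#'
#' The flat prior is placed on `tau` (not `tau^2`); the induced `tau^2`
#' conditional carries the transform factor `(tau^2)^(-1/2)` and is
#' `IG((m-1)/2, sum(beta_k^2/lambda_k^2)/2)`. Requires at least two markers
#' (the conditional is improper at m = 1); a rate floor guards the all-zero
#' beta corner.
#'
#' @param state a `sampler_state` with family bayesU.
#' @return updated state.
#' @export
update_global_bayesU <- function(state) {
  m <- length(state$beta)
  if (m < 2L) stop("flat-tau conditional is improper with fewer than 2 markers")
  s <- sum(state$beta^2 / state$lambda2)
  state$tau2 <- rinvgamma(1, (m - 1) / 2, s / 2)
  state
}

#' Local-scale updates for BayesHP (Horseshoe+)
#'
#' Draws the chained local quantities from their inverse-gamma full
#' conditionals:
#' `lambda_k^2 | . ~ IG(1, 1/theta_k + beta_k^2/(2 tau^2))`,
#' `theta_k | . ~ IG(1, 1/eta_k^2 + 1/lambda_k^2)`,
#' `eta_k^2 | . ~ IG(1, 1/nu_k + 1/theta_k)`,
#' `nu_k | . ~ IG(1, 1 + 1/eta_k^2)`.
#'
#' @inheritParams update_locals_bayesU
#' @return updated state.
#' @export
update_locals_bayesHP <- function(state, k = seq_along(state$beta)) {
  nk <- length(k)
  b2 <- state$beta[k]^2
  state$lambda2[k] <- clamp_lambda2(
    rinvgamma(nk, 1, 1 / state$theta[k] + b2 / (2 * state$tau2)))
  state$theta[k] <- rinvgamma(nk, 1, 1 / state$eta2[k] + 1 / state$lambda2[k])
  state$eta2[k] <- rinvgamma(nk, 1, 1 / state$nu_aux[k] + 1 / state$theta[k])
  state$nu_aux[k] <- rinvgamma(nk, 1, 1 + 1 / state$eta2[k])
  state
}

#' Global-scale update for BayesHP / BayesHE
#'
#' The global scale has the half-Cauchy prior `tau ~ C+(0, 1/N)` with N the
#' training size, represented as `tau^2 ~ IG(1/2, 1/xi)`,
#' `xi ~ IG(1/2, N^2)`. Full conditionals:
#' `tau^2 | . ~ IG((m+1)/2, 1/xi + sum(beta_k^2/lambda_k^2)/2)` and
#' `xi | . ~ IG(1, N^2 + 1/tau^2)`.
#'
#' @param state a `sampler_state` with family bayesHP or bayesHE.
#' @return updated state.
#' @export
update_global_bayesHP <- function(state) {
  m <- length(state$beta)
  N <- state$data$N
  s <- sum(state$beta^2 / state$lambda2)
  state$tau2 <- rinvgamma(1, (m + 1) / 2, 1 / state$xi + s / 2)
  state$xi <- rinvgamma(1, 1, N^2 + 1 / state$tau2)
  state
}

#' Local-scale updates for BayesHE (half-t with df upsilon)
#'
#' Draws `lambda_k^2 | . ~ IG(upsilon/2 + 1/2,
#' upsilon/theta_k + beta_k^2/(2 tau^2))` and
#' `theta_k | . ~ IG(upsilon/2 + 1/2, 1 + upsilon/lambda_k^2)`.
#'
#' @inheritParams update_locals_bayesU
#' @return updated state.
#' @export
update_locals_bayesHE <- function(state, k = seq_along(state$beta)) {
  nk <- length(k)
  u <- state$upsilon
  b2 <- state$beta[k]^2
  state$lambda2[k] <- clamp_lambda2(
    rinvgamma(nk, u / 2 + 0.5, u / state$theta[k] + b2 / (2 * state$tau2)))
  state$theta[k] <- rinvgamma(nk, u / 2 + 0.5, 1 + u / state$lambda2[k])
  state
}

#' Log full conditional of the half-t degrees of freedom
#'
#' Up to an additive constant,
#' `(upsilon m / 2 + a - 1) log(upsilon) - m log Gamma(upsilon/2)
#'  - upsilon * (0.5 sum log(theta_k lambda_k^2)
#'               + sum 1/(theta_k lambda_k^2) + b)`,
#' the kernel obtained by multiplying the `IG(upsilon/2, upsilon/theta_k)`
#' densities of the `lambda_k^2` with the `Gamma(a, b)` prior of `upsilon`.
#' With m = 0 it reduces to the Gamma(a, b) log-kernel.
#'
#' @param upsilon positive scalar (vectorised over `upsilon`).
#' @param theta,lambda2 positive vectors of length m.
#' @param a,b gamma shape and rate of the `upsilon` prior.
#' @param m number of markers; defaults to `length(lambda2)`.
#' @return log-density values up to a constant.
#' @export
log_conditional_df <- function(upsilon, theta, lambda2, a, b,
                               m = length(lambda2)) {
  if (any(!is.finite(upsilon)) || any(upsilon <= 0))
    stop("upsilon must be positive and finite")
  if (m > 0 && (any(!is.finite(theta)) || any(!is.finite(lambda2)) ||
                any(theta <= 0) || any(lambda2 <= 0)))
    stop("theta and lambda2 must be positive and finite")
  if (m == 0) {
    slog <- 0; srec <- 0
  } else {
    slog <- sum(log(theta * lambda2))
    srec <- sum(1 / (theta * lambda2))
  }
  (upsilon * m / 2 + a - 1) * log(upsilon) - m * lgamma(upsilon / 2) -
    upsilon * (0.5 * slog + srec + b)
}

#' Metropolis-Hastings step for the degrees of freedom
#'
#' Random-walk proposal on `zeta = log(upsilon)` with standard deviation
#' `mh_step`; the acceptance ratio uses the zeta-space target, i.e. the
#' log conditional of `upsilon` plus the Jacobian term `zeta`. Proposals
#' outside the supported range [0.05, 200] are rejected. On rejection the
#' returned value equals the input.
#'
#' @param state a `sampler_state` with family bayesHE (or any state carrying
#'   `upsilon`, `theta`, `lambda2`).
#' @param a,b gamma shape and rate of the `upsilon` prior.
#' @param mh_step proposal standard deviation on the log scale.
#' @param m number of markers entering the conditional (defaults to all;
#'   `m = 0` targets the prior alone).
#' @return list (`df_sample_result`) with `new_upsilon`, `accepted`,
#'   `log_ratio`.
#' @export
sample_df_mh <- function(state, a, b, mh_step, m = length(state$lambda2)) {
  u0 <- state$upsilon
  z0 <- log(u0)
  z1 <- z0 + rnorm(1, 0, mh_step)
  u1 <- exp(z1)
  if (u1 < .UPSILON_MIN || u1 > .UPSILON_MAX) {
    return(structure(list(new_upsilon = u0, accepted = FALSE,
                          log_ratio = -Inf), class = "df_sample_result"))
  }
  th <- state$theta[seq_len(m)]; l2 <- state$lambda2[seq_len(m)]
  lr <- (log_conditional_df(u1, th, l2, a, b, m) + z1) -
        (log_conditional_df(u0, th, l2, a, b, m) + z0)
  accepted <- log(runif(1)) < lr
  structure(list(new_upsilon = if (accepted) u1 else u0,
                 accepted = accepted, log_ratio = lr),
            class = "df_sample_result")
}
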