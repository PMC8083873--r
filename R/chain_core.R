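# Shared Gibbs engine for the whole-genome regression
#   y = mu * 1 + X beta + e,   e ~ N(0, D sigma2_e),  D = diag(d_ii)
# parameterised by a prior family plug-in (bayesA/B, bayesU, bayesHP,
# bayesHE). Genotype columns are centred by 2 p_k (training frequencies)
# before sampling. Fixed update order per sweep:
#   mu -> marker loop (beta_k) -> local scales -> global scales ->
#   df hyperparameter (bayesHE) -> sigma2_e.

#' Model specification
#'
#' Describes which prior family to fit and its hyperparameters.
#'
#' Families:
#' \describe{
#'   \item{bayesU}{Horseshoe: `beta_k ~ N(0, lambda_k^2 tau^2)`,
#'     `lambda_k ~ C+(0,1)`, flat prior on `tau`.}
#'   \item{bayesHP}{Horseshoe+: a second half-Cauchy local layer
#'     `lambda_k ~ C+(0, eta_k)`, `eta_k ~ C+(0,1)`; global
#'     `tau ~ C+(0, 1/N)` with N the training size.}
#'   \item{bayesHE}{half-t local prior `lambda_k ~ half-t(upsilon, 1)` with
#'     unknown degrees of freedom `upsilon ~ Gamma(a, b)` (b a rate, prior
#'     mean a/b), sampled by random-walk Metropolis-Hastings on
#'     `log(upsilon)`; global as in bayesHP.}
#'   \item{bayesA}{scaled-t prior via per-marker variances
#'     `sigma2_beta_k ~ IG(df/2, df * s2_beta / 2)`.}
#'   \item{bayesB}{spike-and-t: marker excluded with probability `pi`,
#'     otherwise the bayesA slab.}
#'   \item{gblup}{handled by [solve_mme()] / [estimate_vc_em()], not by the
#'     Gibbs engine.}
#' }
#'
#' @param family prior family, see Details.
#' @param pi bayesB exclusion probability (default 0.95).
#' @param a,b gamma shape and rate of the `upsilon` prior for bayesHE
#'   (defaults 4 and 1, prior mean 4).
#' @param df_ab degrees of freedom of the bayesA/B scaled-t prior.
#' @param s2_beta scale of the bayesA/B t prior; when NULL it is set at
#'   initialisation so the implied total marker variance is `h2_prior` of
#'   `var(y)`: `s2_beta = h2_prior var(y) (df-2) / (df sum 2 p_k (1-p_k))`.
#' @param h2_prior assumed genetic proportion used to derive `s2_beta`.
#' @param mh_step proposal s.d. of the random walk on `log(upsilon)`.
#' @param adapt_mh Robbins-Monro adaptation of `mh_step` during burn-in
#'   toward 0.44 acceptance; frozen afterwards.
#' @param prior_mu length-2 `c(mean, variance)` normal prior for the
#'   intercept; variance `Inf` (default) is the flat prior.
#' @param prior_sigma2e length-2 `c(shape, rate)` inverse-gamma prior for
#'   `sigma2_e`; `c(0, 0)` (default) is the scale-uniform Jeffreys prior.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(family = c("bayesU", "bayesHP", "bayesHE", "bayesA",
                                  "bayesB", "gblup"),
                       pi = 0.95, a = 4, b = 1, df_ab = 4.2, s2_beta = NULL,
                       h2_prior = 0.5, mh_step = 0.5, adapt_mh = TRUE,
                       prior_mu = c(0, Inf), prior_sigma2e = c(0, 0)) {
  family <- match.arg(family)
  stopifnot(pi >= 0, pi < 1, a > 0, b > 0, df_ab > 0, mh_step > 0,
            is.null(s2_beta) || s2_beta > 0, h2_prior > 0, h2_prior < 1,
            length(prior_mu) == 2, length(prior_sigma2e) == 2,
            prior_mu[2] > 0, prior_sigma2e[1] >= 0, prior_sigma2e[2] >= 0)
  structure(list(family = family, pi = pi, a = a, b = b, df_ab = df_ab,
                 s2_beta = s2_beta, h2_prior = h2_prior, mh_step = mh_step,
                 adapt_mh = adapt_mh, prior_mu = prior_mu,
                 prior_sigma2e = prior_sigma2e),
            class = "model_spec")
}

#' Chain configuration
#'
#' @param n_iter total MCMC sweeps (default 50000).
#' @param burn_in discarded sweeps (default 20000).
#' @param thin saving stride after burn-in (default 50, so the default chain
#'   saves 600 draws).
#' @param seed RNG seed for the chain.
#' @param fast logical; TRUE replaces the defaults with the desk-scale
#'   preset 5000/2000/10.
#' @return object of class `chain_config`.
#' @export
chain_config <- function(n_iter = 50000L, burn_in = 20000L, thin = 50L,
                         seed = 1L, fast = FALSE) {
  if (fast) { n_iter <- 5000L; burn_in <- 2000L; thin <- 10L }
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (thin < 1L) stop("thin must be >= 1")
  if ((n_iter - burn_in) %/% thin < 10L)
    stop("chain too short: fewer than 10 saved samples")
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed)),
            class = "chain_config")
}

#' Initialise the sampler state
#'
#' Aligns genotypes and phenotypes by id, centres genotype columns by
#' `2 p_k`, and initialises every latent quantity: `mu` at the weighted mean
#' of y, all effects at zero, every auxiliary scale at one, `upsilon` at its
#' prior mean `a/b`, `sigma2_e` at the sample variance of y, residuals
#' consistent with `y - mu - X beta`.
#'
#' @param g a [genotype_matrix()] without missing codes.
#' @param ph a [phenotype_table()].
#' @param spec a [model_spec()].
#' @param cfg a [chain_config()].
#' @return a `sampler_state` list; `$data` carries the centred design.
#' @export
init_state <- function(g, ph, spec, cfg) {
  if (anyNA(g$codes)) stop("genotypes contain missing codes; impute first")
  ids <- intersect(g$individual_ids, ph$individual_id)
  if (length(ids) == 0L) stop("no individuals shared between genotypes and phenotypes")
  if (length(ids) < 2L) stop("need at least 2 aligned individuals")
  gi <- match(ids, g$individual_ids)
  pi_ <- match(ids, ph$individual_id)
  codes <- g$codes[gi, , drop = FALSE]
  p <- colMeans(codes) / 2
  X <- sweep(codes, 2L, 2 * p)
  y <- ph$y[pi_]
  d <- ph$weight[pi_]
  w <- 1 / d
  n <- length(y); m <- ncol(X)
  if (is.null(spec$s2_beta) && spec$family %in% c("bayesA", "bayesB")) {
    het <- sum(2 * p * (1 - p))
    if (het <= 0) stop("all markers monomorphic; cannot scale s2_beta")
    df <- spec$df_ab
    spec$s2_beta <- spec$h2_prior * var(y) * max(df - 2, 0.1) / (df * het)
  }
  mu0 <- sum(w * y) / sum(w)
  state <- list(
    mu = mu0,
    beta = numeric(m),
    lambda2 = rep(1, m),
    theta = rep(1, m),
    eta2 = rep(1, m),
    nu_aux = rep(1, m),
    tau2 = 1,
    xi = 1,
    upsilon = spec$a / spec$b,
    delta = rep(1L, m),
    sigma2_beta_k = rep(if (is.null(spec$s2_beta)) 1 else spec$s2_beta, m),
    sigma2_e = var(y),
    resid = y - mu0,
    mh_step = spec$mh_step,
    data = list(X = X, y = y, w = w, d = d, n = n, m = m, N = n,
                freqs = p, individual_ids = ids,
                marker_ids = g$marker_ids,
                xtwx = colSums(X * X * w)),
    spec = spec, cfg = cfg)
  class(state) <- "sampler_state"
  state
}

# conditional moments of mu given everything else (normal)
conditional_intercept <- function(state) {
  d <- state$data
  prior <- state$spec$prior_mu
  r_full <- state$resid + state$mu  # y - X beta
  sw <- sum(d$w)
  prec <- sw / state$sigma2_e + if (is.finite(prior[2])) 1 / prior[2] else 0
  num <- sum(d$w * r_full) / state$sigma2_e +
    if (is.finite(prior[2])) prior[1] / prior[2] else 0
  list(mean = num / prec, var = 1 / prec)
}

#' Gibbs update of the intercept
#'
#' Draws `mu` from its normal full conditional under residual weights
#' `1/d_ii` (flat prior by default) and shifts residuals so that
#' `resid = y - mu - X beta` still holds.
#'
#' @param state a `sampler_state`.
#' @return updated state.
#' @export
update_intercept <- function(state) {
  cm <- conditional_intercept(state)
  new_mu <- rnorm(1, cm$mean, sqrt(cm$var))
  state$resid <- state$resid + state$mu - new_mu
  state$mu <- new_mu
  state
}

# conditional moments of beta_k (normal), given prior variance v_k
conditional_marker_effect <- function(state, k, prior_var) {
  d <- state$data
  xk <- d$X[, k]
  r_k <- state$resid + xk * state$beta[k]  # residuals with marker k removed
  c_k <- unname(d$xtwx[k])
  v <- 1 / (c_k / state$sigma2_e + 1 / prior_var)
  list(mean = v * sum(d$w * xk * r_k) / state$sigma2_e, var = v)
}

#' Gibbs update of one marker effect
#'
#' Draws `beta_k` from its normal full conditional with weighted
#' cross-products, prior variance `prior_var` (which is
#' `lambda_k^2 tau^2` for the global-local families or `sigma2_beta_k`
#' for bayesA/B) and residual variance `sigma2_e`; residuals are updated
#' incrementally.
#'
#' @param state a `sampler_state`.
#' @param k marker index.
#' @param prior_var positive prior variance of the effect.
#' @return updated state.
#' @export
update_marker_effect <- function(state, k, prior_var) {
  if (!is.finite(prior_var) || prior_var <= 0)
    stop("prior_var must be positive and finite")
  cm <- conditional_marker_effect(state, k, prior_var)
  new_b <- rnorm(1, cm$mean, sqrt(cm$var))
  state$resid <- state$resid + state$data$X[, k] * (state$beta[k] - new_b)
  state$beta[k] <- new_b
  state
}

# IG(shape, rate) of the sigma2_e full conditional
conditional_residual_variance <- function(state) {
  d <- state$data
  pr <- state$spec$prior_sigma2e
  list(shape = d$n / 2 + pr[1],
       rate = sum(d$w * state$resid^2) / 2 + pr[2])
}

#' Gibbs update of the residual variance
#'
#' Draws `sigma2_e` from its inverse-gamma full conditional with the
#' weighted residual sum of squares `sum(e_i^2 / d_ii)`; the default prior
#' is the scale-uniform Jeffreys prior, proportional to `1/sigma2_e`.
#'
#' @param state a `sampler_state`.
#' @return updated state.
#' @export
update_residual_variance <- function(state) {
  cp <- conditional_residual_variance(state)
  state$sigma2_e <- rinvgamma(1, cp$shape, cp$rate)
  state
}

# prior variance vector of beta for the current family/state
prior_var_vector <- function(state) {
  switch(state$spec$family,
    bayesU = , bayesHP = , bayesHE = clamp_lambda2(state$lambda2) * state$tau2,
    bayesA = , bayesB = state$sigma2_beta_k,
    stop("no Gibbs prior variance for family ", state$spec$family))
}

# One full Gibbs sweep in R, via the granular update functions. The
# production chain (run_chain) replaces the marker loop with the compiled
# sweep; a test asserts both paths draw identically on a shared RNG stream.
gibbs_sweep_r <- function(state) {
  state <- update_intercept(state)
  fam <- state$spec$family
  if (fam == "bayesB") {
    for (k in seq_len(state$data$m)) state <- update_bayesB_indicator(state, k)
    state <- update_bayesA_variance(state)
  } else {
    pv <- prior_var_vector(state)
    for (k in seq_len(state$data$m))
      state <- update_marker_effect(state, k, pv[k])
    state <- switch(fam,
      bayesU = update_global_bayesU(update_locals_bayesU(state)),
      bayesHP = update_global_bayesHP(update_locals_bayesHP(state)),
      bayesHE = {
        s <- update_global_bayesHP(update_locals_bayesHE(state))
        res <- sample_df_mh(s, s$spec$a, s$spec$b, s$mh_step)
        s$upsilon <- res$new_upsilon
        s
      },
      bayesA = update_bayesA_variance(state))
  }
  update_residual_variance(state)
}

#' Run a Gibbs chain
#'
#' Executes `cfg$n_iter` full sweeps in the fixed update order
#' (intercept, marker effects, local scales, global scales, degrees of
#' freedom for bayesHE, residual variance), discards `cfg$burn_in`, saves
#' every `cfg$thin`-th remaining draw, and records traces of the overall
#' mean and of the additive variance `Vg = var(X beta)`. Deterministic
#' given `cfg$seed`.
#'
#' @param g a [genotype_matrix()] (no missing codes).
#' @param ph a [phenotype_table()].
#' @param spec a [model_spec()] for one of the Gibbs families.
#' @param cfg a [chain_config()].
#' @param keep_samples keep the saved draws of beta? (posterior mean is
#'   always returned; the full draws add memory).
#' @return object of class `posterior_summary`: posterior-mean effects
#'   `beta_mean`, `mu_mean`, `sigma2_e_mean`, `tau2_mean`, `upsilon_mean`
#'   and `acceptance_rate` (bayesHE), traces `mu_trace`, `vg_trace`,
#'   `sigma2_e_trace`, `upsilon_trace`, and `n_saved`.
#' @export
run_chain <- function(g, ph, spec, cfg, keep_samples = FALSE) {
  if (spec$family == "gblup")
    stop("gblup is fitted with solve_mme()/estimate_vc_em(), not run_chain()")
  set.seed(cfg$seed)
  state <- init_state(g, ph, spec, cfg)
  d <- state$data
  n_saved <- (cfg$n_iter - cfg$burn_in) %/% cfg$thin
  mu_trace <- numeric(n_saved); vg_trace <- numeric(n_saved)
  se_trace <- numeric(n_saved); up_trace <- numeric(n_saved)
  tau2_acc <- 0; beta_acc <- numeric(d$m)
  beta2_acc <- numeric(d$m); mu_acc <- 0; se_acc <- 0; up_acc <- 0
  mh_accept <- 0L; mh_total <- 0L
  draws <- if (keep_samples) matrix(NA_real_, n_saved, d$m) else NULL
  fam <- spec$family
  isave <- 0L
  for (it in seq_len(cfg$n_iter)) {
    state <- update_intercept(state)
    if (fam == "bayesB") {
      sw <- bayesb_sweep_cpp(d$X, d$w, d$xtwx, state$resid, state$beta,
                             state$delta, state$sigma2_beta_k,
                             state$sigma2_e, spec$pi)
      state$beta <- sw$beta; state$resid <- sw$resid; state$delta <- sw$delta
      state <- update_bayesA_variance(state)
    } else {
      pv <- prior_var_vector(state)
      sw <- marker_sweep_cpp(d$X, d$w, d$xtwx, state$resid, state$beta, pv,
                             state$sigma2_e)
      state$beta <- sw$beta; state$resid <- sw$resid
      if (fam == "bayesU") {
        state <- update_global_bayesU(update_locals_bayesU(state))
      } else if (fam == "bayesHP") {
        state <- update_global_bayesHP(update_locals_bayesHP(state))
      } else if (fam == "bayesHE") {
        state <- update_global_bayesHP(update_locals_bayesHE(state))
        res <- sample_df_mh(state, spec$a, spec$b, state$mh_step)
        state$upsilon <- res$new_upsilon
        if (it <= cfg$burn_in) {
          if (spec$adapt_mh) {
            acc_p <- min(1, exp(res$log_ratio))
            state$mh_step <- exp(log(state$mh_step) +
                                   (acc_p - 0.44) / it^0.6)
          }
        } else {
          mh_total <- mh_total + 1L
          if (res$accepted) mh_accept <- mh_accept + 1L
        }
      } else if (fam == "bayesA") {
        state <- update_bayesA_variance(state)
      }
    }
    state <- update_residual_variance(state)
    if (!all(is.finite(state$beta)) || !is.finite(state$sigma2_e))
      stop("chain diverged (non-finite state) at iteration ", it)
    if (it > cfg$burn_in && (it - cfg$burn_in) %% cfg$thin == 0L) {
      isave <- isave + 1L
      gv <- d$y - state$mu - state$resid  # X beta, from the residual identity
      mu_trace[isave] <- state$mu
      vg_trace[isave] <- var(gv)
      se_trace[isave] <- state$sigma2_e
      up_trace[isave] <- state$upsilon
      beta_acc <- beta_acc + state$beta
      beta2_acc <- beta2_acc + state$beta^2
      mu_acc <- mu_acc + state$mu
      se_acc <- se_acc + state$sigma2_e
      up_acc <- up_acc + state$upsilon
      tau2_acc <- tau2_acc + state$tau2
      if (keep_samples) draws[isave, ] <- state$beta
    }
  }
  structure(list(
    family = fam,
    beta_mean = beta_acc / n_saved,
    beta_sd = sqrt(pmax(beta2_acc / n_saved - (beta_acc / n_saved)^2, 0)),
    mu_mean = mu_acc / n_saved,
    sigma2_e_mean = se_acc / n_saved,
    tau2_mean = tau2_acc / n_saved,
    upsilon_mean = if (fam == "bayesHE") up_acc / n_saved else NA_real_,
    acceptance_rate = if (fam == "bayesHE") mh_accept / max(mh_total, 1L)
                      else NA_real_,
    mu_trace = mu_trace, vg_trace = vg_trace,
    sigma2_e_trace = se_trace,
    upsilon_trace = if (fam == "bayesHE") up_trace else NULL,
    n_saved = n_saved,
    freqs = d$freqs, marker_ids = d$marker_ids,
    draws = draws,
    spec = spec, cfg = cfg), class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("posterior_summary [", x$family, "]: ", length(x$beta_mean),
      " markers, ", x$n_saved, " saved draws\n",
      "  mu = ", signif(x$mu_mean, 4),
      ", sigma2_e = ", signif(x$sigma2_e_mean, 4),
      ", mean Vg = ", signif(mean(x$vg_trace), 4), "\n", sep = "")
  if (x$family == "bayesHE")
    cat("  upsilon = ", signif(x$upsilon_mean, 4),
        " (MH acceptance ", signif(x$acceptance_rate, 3), ")\n", sep = "")
  invisible(x)
}

#' Direct genomic values
#'
#' `DGV_i = sum_k x_ik beta_k`. The intercept is excluded: the accuracy and
#' bias metrics are location-invariant. When `center` (a vector of training
#' `2 p_k`) is supplied, columns are centred with the training frequencies
#' first, which only shifts all DGVs by a common constant.
#'
#' @param g a [genotype_matrix()] whose markers match `beta`.
#' @param beta effect vector (length = number of markers).
#' @param center optional vector of training column means `2 p_k`.
#' @return named numeric vector of DGVs.
#' @export
genomic_values <- function(g, beta, center = NULL) {
  m <- ncol(g$codes)
  if (length(beta) != m)
    stop("marker-set mismatch: ", m, " markers vs ", length(beta), " effects")
  X <- g$codes
  if (!is.null(center)) {
    if (length(center) != m) stop("center length must match marker count")
    X <- sweep(X, 2L, center)
  }
  dgv <- drop(X %*% beta)
  names(dgv) <- g$individual_ids
  dgv
}

#' Additive genetic variance of a marker-effect vector
#'
#' The empirical variance across individuals of `sum_k x_ik beta_k`
#' (denominator n-1). This is the quantity traced per saved draw by
#' [run_chain()].
#'
#' @inheritParams genomic_values
#' @return scalar variance.
#' @export
additive_variance <- function(g, beta) {
  if (nrow(g$codes) < 2L) stop("additive variance undefined for n < 2")
  var(genomic_values(g, beta))
}

#' Write posterior traces as CSV with a JSON metadata sidecar
#'
#' @param fit a `posterior_summary`.
#' @param path CSV output path; metadata goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_posterior_csv <- function(fit, path) {
  tr <- data.table::data.table(
    saved = seq_len(fit$n_saved), mu = fit$mu_trace, vg = fit$vg_trace,
    sigma2_e = fit$sigma2_e_trace)
  if (!is.null(fit$upsilon_trace)) tr$upsilon <- fit$upsilon_trace
  data.table::fwrite(tr, path, quote = FALSE)
  eff <- data.table::data.table(marker_id = fit$marker_ids,
                                beta_mean = fit$beta_mean,
                                beta_sd = fit$beta_sd)
  data.table::fwrite(eff, sub("(\\.csv)?$", "_effects.csv", path),
                     quote = FALSE)
  meta <- list(family = fit$family,
               spec = unclass(fit$spec), cfg = unclass(fit$cfg),
               n_saved = fit$n_saved,
               mu_mean = fit$mu_mean, sigma2_e_mean = fit$sigma2_e_mean,
               upsilon_mean = fit$upsilon_mean,
               acceptance_rate = fit$acceptance_rate)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
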