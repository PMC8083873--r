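# GBLUP: VanRaden genomic relationship matrix, weighted mixed-model
# equations and EM-REML variance components for the model
#   y = mu 1 + g + e,  g ~ N(0, G sigma2_g),  e ~ N(0, D sigma2_e).

#' VanRaden genomic relationship matrix
#'
#' `G = (M - P)(M - P)' / (2 sum p_k (1 - p_k))`, where M holds the 0/1/2
#' codes and the k-th column of P is `2 p_k` with `p_k` the counted-allele
#' frequency.
#'
#' @param g a [genotype_matrix()] without missing codes.
#' @return object of class `grm` with fields `matrix`, `scale`
#'   (`2 sum p_k (1-p_k)`), `ids`.
#' @export
build_grm <- function(g) {
  if (anyNA(g$codes)) stop("genotypes contain missing codes; impute first")
  p <- colMeans(g$codes) / 2
  scale <- 2 * sum(p * (1 - p))
  if (scale <= 0)
    stop("all markers monomorphic: GRM denominator is zero")
  Z <- sweep(g$codes, 2L, 2 * p)
  G <- tcrossprod(Z) / scale
  dimnames(G) <- list(g$individual_ids, g$individual_ids)
  structure(list(matrix = G, scale = scale, ids = g$individual_ids),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", nrow(x$matrix), "individuals, mean diagonal",
      signif(mean(diag(x$matrix)), 4), "\n")
  invisible(x)
}

#' Write a GRM as a triplet CSV
#' @param grm a `grm`.
#' @param path output path; columns id1, id2, value (lower triangle incl.
#'   diagonal).
#' @return `path`, invisibly.
#' @export
write_grm_csv <- function(grm, path) {
  idx <- which(lower.tri(grm$matrix, diag = TRUE), arr.ind = TRUE)
  data.table::fwrite(
    data.table::data.table(id1 = grm$ids[idx[, 1]], id2 = grm$ids[idx[, 2]],
                           value = grm$matrix[idx]),
    path, quote = FALSE)
  invisible(path)
}

# align a phenotype table to the GRM ids; error if none shared
.align_grm_ph <- function(grm, ph) {
  ids <- intersect(grm$ids, ph$individual_id)
  if (length(ids) < 2L) stop("fewer than 2 individuals shared with the GRM")
  list(ids = ids,
       G = grm$matrix[match(ids, grm$ids), match(ids, grm$ids), drop = FALSE],
       y = ph$y[match(ids, ph$individual_id)],
       d = ph$weight[match(ids, ph$individual_id)])
}

#' Solve the weighted mixed-model equations
#'
#' Returns the BLUE of the overall mean and the BLUPs of the genomic values
#' under `g ~ N(0, G sigma2_g)`, `e ~ N(0, D sigma2_e)`. Before solving, G
#' is blended as `(1 - stabilize) G + stabilize I`; the default 0.01 keeps
#' the system non-singular when G is rank-deficient (m < n, duplicated
#' genotypes). Set `stabilize = 0` to solve on G as-is.
#'
#' @param grm a `grm` (see [build_grm()]).
#' @param ph a [phenotype_table()] (ids matched against the GRM).
#' @param sigma2_g,sigma2_e positive variance components.
#' @param stabilize blending weight toward the identity.
#' @return list with `mu_hat`, `g_hat` (named by id), `ids`.
#' @export
solve_mme <- function(grm, ph, sigma2_g, sigma2_e, stabilize = 0.01) {
  stopifnot(sigma2_g > 0, sigma2_e > 0, stabilize >= 0, stabilize < 1)
  al <- .align_grm_ph(grm, ph)
  n <- length(al$y)
  G <- (1 - stabilize) * al$G + diag(stabilize, n)
  # solve through V = G sg2 + D se2: no G inverse needed, works at any rank
  V <- G * sigma2_g + diag(al$d * sigma2_e, n)
  Vi <- tryCatch(chol2inv(chol(V)),
                 error = function(e) stop("mixed-model system singular even ",
                                          "after stabilization: ",
                                          conditionMessage(e)))
  one <- rep(1, n)
  Vi1 <- Vi %*% one
  mu_hat <- drop(crossprod(one, Vi %*% al$y)) / drop(crossprod(one, Vi1))
  g_hat <- drop(sigma2_g * G %*% (Vi %*% (al$y - mu_hat)))
  names(g_hat) <- al$ids
  list(mu_hat = mu_hat, g_hat = g_hat, ids = al$ids)
}

# restricted log-likelihood of (sigma2_g, sigma2_e) on the eigen-transformed
# scale (constant offsets from the D-transform dropped)
.reml_loglik <- function(lam, yt, ot, sg2, se2) {
  dvec <- sg2 * lam + se2
  Vi_y <- yt / dvec; Vi_o <- ot / dvec
  oVo <- sum(ot * Vi_o)
  # P y = V^-1 y - V^-1 1 (1' V^-1 1)^-1 1' V^-1 y
  oVy <- sum(ot * Vi_y)
  yPy <- sum(yt * Vi_y) - oVy^2 / oVo
  -0.5 * (sum(log(dvec)) + log(oVo) + yPy)
}

#' EM-REML variance components for GBLUP
#'
#' Estimates `sigma2_g` and `sigma2_e` by EM-REML for the single-random-
#' effect model above. The computation whitens by `D^(-1/2)`, eigen-
#' decomposes the transformed relationship matrix once, and then iterates
#' the EM updates in O(n) per iteration. The restricted log-likelihood is
#' checked to be non-decreasing at every iteration.
#'
#' @param grm a `grm`.
#' @param ph a [phenotype_table()].
#' @param max_iter maximum EM iterations.
#' @param tol relative-change convergence tolerance.
#' @param stabilize identity blend applied to G (see [solve_mme()]).
#' @return list with `sigma2_g`, `sigma2_e`, `converged`, `n_iter`,
#'   `loglik` (trace of restricted log-likelihoods).
#' @export
estimate_vc_em <- function(grm, ph, max_iter = 200L, tol = 1e-8,
                           stabilize = 0.01) {
  al <- .align_grm_ph(grm, ph)
  n <- length(al$y)
  if (n < 10L) stop("EM-REML needs at least 10 records")
  if (var(al$y) <= 0) stop("response has zero variance")
  G <- (1 - stabilize) * al$G + diag(stabilize, n)
  s <- 1 / sqrt(al$d)
  Gs <- t(G * s) * s          # D^-1/2 G D^-1/2
  es <- eigen(Gs, symmetric = TRUE)
  lam <- pmax(es$values, 0)
  yt <- drop(crossprod(es$vectors, al$y * s))
  ot <- drop(crossprod(es$vectors, s))
  vy <- var(al$y)
  sg2 <- vy / 2; se2 <- vy / 2
  ll <- .reml_loglik(lam, yt, ot, sg2, se2)
  ll_trace <- ll
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dvec <- sg2 * lam + se2
    Vi_y <- yt / dvec; Vi_o <- ot / dvec
    oVo <- sum(ot * Vi_o)
    Py <- Vi_y - Vi_o * (sum(ot * Vi_y) / oVo)
    # tr(P A) = tr(V^-1 A) - (1'V^-1 A V^-1 1)/(1'V^-1 1), A diagonal here
    tr_PG <- sum(lam / dvec) - sum(Vi_o^2 * lam) / oVo
    tr_PI <- sum(1 / dvec) - sum(Vi_o^2) / oVo
    sg2_new <- sg2 + (sg2^2 / n) * (sum(Py^2 * lam) - tr_PG)
    se2_new <- se2 + (se2^2 / n) * (sum(Py^2) - tr_PI)
    sg2_new <- max(sg2_new, 1e-10 * vy)
    se2_new <- max(se2_new, 1e-10 * vy)
    ll_new <- .reml_loglik(lam, yt, ot, sg2_new, se2_new)
    if (ll_new < ll - 1e-8 * abs(ll))
      stop("EM-REML log-likelihood decreased; numerical failure")
    rel <- max(abs(sg2_new - sg2), abs(se2_new - se2)) /
      max(sg2 + se2, .Machine$double.eps)
    sg2 <- sg2_new; se2 <- se2_new; ll <- ll_new
    ll_trace <- c(ll_trace, ll)
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM-REML did not converge in ", max_iter, " iterations")
  list(sigma2_g = sg2, sigma2_e = se2, converged = converged,
       n_iter = length(ll_trace) - 1L, loglik = ll_trace)
}

#' Fit GBLUP and predict test individuals
#'
#' Convenience wrapper used by the cross-validation harness: estimates
#' variance components on the training records (or uses supplied ones),
#' solves the MME, and predicts genomic values of individuals without
#' phenotypes through `g_test = sigma2_g G_test,train V_train^-1 (y - mu)`.
#'
#' @param g a [genotype_matrix()] holding training and test individuals.
#' @param ph_train a [phenotype_table()] of the training records.
#' @param test_ids ids to predict.
#' @param sigma2_g,sigma2_e optional fixed variance components; estimated by
#'   [estimate_vc_em()] when NULL.
#' @param stabilize identity blend for G.
#' @return list with `dgv` (named predictions for `test_ids`), `mu_hat`,
#'   `g_hat` (training BLUPs), `sigma2_g`, `sigma2_e`.
#' @export
gblup_predict <- function(g, ph_train, test_ids, sigma2_g = NULL,
                          sigma2_e = NULL, stabilize = 0.01) {
  grm <- build_grm(g)
  if (is.null(sigma2_g) || is.null(sigma2_e)) {
    vc <- estimate_vc_em(grm, ph_train, stabilize = stabilize)
    sigma2_g <- vc$sigma2_g; sigma2_e <- vc$sigma2_e
  }
  al <- .align_grm_ph(grm, ph_train)
  n <- length(al$y)
  Gtt <- (1 - stabilize) * al$G + diag(stabilize, n)
  V <- Gtt * sigma2_g + diag(al$d * sigma2_e, n)
  Vi <- chol2inv(chol(V))
  one <- rep(1, n)
  mu_hat <- drop(crossprod(one, Vi %*% al$y)) / drop(sum(Vi %*% one))
  rhs <- drop(Vi %*% (al$y - mu_hat))
  test_ids <- as.character(test_ids)
  if (!all(test_ids %in% grm$ids)) stop("test ids missing from the GRM")
  Gxt <- grm$matrix[match(test_ids, grm$ids), match(al$ids, grm$ids),
                    drop = FALSE] * (1 - stabilize)
  dgv <- drop(sigma2_g * Gxt %*% rhs)
  names(dgv) <- test_ids
  g_hat <- drop(sigma2_g * Gtt %*% rhs)
  names(g_hat) <- al$ids
  list(dgv = dgv, mu_hat = mu_hat, g_hat = g_hat,
       sigma2_g = sigma2_g, sigma2_e = sigma2_e)
}
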