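# Cross-validation harness and the accuracy / bias metrics of genomic
# evaluation, plus the DRP reliability / effective-record-contribution
# algebra.

#' Random cross-validation folds
#'
#' Each replicate is an independent random partition of `n` individuals into
#' `k` near-equal folds (sizes differ by at most one). Deterministic given
#' `seed`. Defaults follow the 5 x 6 scheme: six folds, five replicates.
#'
#' @param n number of individuals.
#' @param k folds per replicate (default 6).
#' @param reps replicates (default 5).
#' @param seed RNG seed.
#' @return list of length `reps`; each element an integer vector of fold
#'   labels (1..k) per individual.
#' @export
make_cv_folds <- function(n, k = 6L, reps = 5L, seed = 1L) {
  stopifnot(k >= 2L, n >= k, reps >= 1L)
  set.seed(seed)
  lapply(seq_len(reps), function(r) {
    sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
    sample(rep.int(seq_len(k), sizes))
  })
}

#' Prediction accuracy
#'
#' Pearson correlation of the test responses with the DGVs. When per-record
#' DRP reliabilities are supplied the correlation is divided by
#' `r_bar = mean(sqrt(r2))` over the test set, the standard correction used
#' with de-regressed proofs; without reliabilities the plain correlation is
#' returned (the convention for phenotypes / pre-corrected phenotypes).
#'
#' @param y_test response vector (phenotype or DRP).
#' @param dgv direct genomic values, aligned with `y_test`.
#' @param reliability optional vector of DRP reliabilities in (0, 1].
#' @return scalar accuracy.
#' @export
accuracy <- function(y_test, dgv, reliability = NULL) {
  stopifnot(length(y_test) == length(dgv), length(y_test) >= 3L)
  if (sd(y_test) == 0 || sd(dgv) == 0)
    stop("accuracy undefined: zero variance in response or DGV")
  acc <- cor(y_test, dgv)
  if (!is.null(reliability) && !all(is.na(reliability))) {
    stopifnot(length(reliability) == length(y_test))
    acc <- acc / mean(sqrt(reliability))
  }
  acc
}

#' Prediction bias (regression slope)
#'
#' Slope of the least-squares regression of the response on the DGV,
#' `cov(y_test, dgv)/var(dgv)`. A slope of one indicates unbiased
#' predictions; below one the DGVs are over-dispersed.
#'
#' @inheritParams accuracy
#' @return scalar slope.
#' @export
bias <- function(y_test, dgv) {
  stopifnot(length(y_test) == length(dgv))
  if (var(dgv) == 0) stop("bias undefined: zero variance in DGV")
  cov(y_test, dgv) / var(dgv)
}

#' DRP reliability from the effective record contribution
#'
#' `r2_DRP = ERC / (ERC + lambda)` with `lambda = (1 - h2)/h2`.
#'
#' @param erc positive effective record contribution(s).
#' @param h2 trait heritability in (0, 1).
#' @return reliabilities in (0, 1).
#' @export
drp_reliability <- function(erc, h2) {
  stopifnot(all(erc > 0), h2 > 0, h2 < 1)
  lambda <- (1 - h2) / h2
  erc / (erc + lambda)
}

#' Effective record contribution from an EBV reliability
#'
#' `ERC = lambda * REL / (1 - REL)` with `lambda = (1 - h2)/h2`; the inverse
#' of [drp_reliability()].
#'
#' @param rel reliability in (0, 1).
#' @param h2 trait heritability in (0, 1).
#' @return positive ERC value(s).
#' @export
erc_from_rel <- function(rel, h2) {
  stopifnot(h2 > 0, h2 < 1)
  if (any(rel <= 0) || any(rel >= 1))
    stop("reliability must lie strictly inside (0, 1)")
  lambda <- (1 - h2) / h2
  lambda * rel / (1 - rel)
}

# fit one Gibbs-family model on the training split and return test DGVs;
# training allele frequencies centre both splits
.fit_predict <- function(g, ph_train, test_ids, spec, cfg) {
  if (spec$family == "gblup") {
    pred <- gblup_predict(
      .subset_genotypes(g, c(ph_train$individual_id, test_ids)),
      ph_train, test_ids)
    return(pred$dgv)
  }
  g_train <- .subset_genotypes(g, ph_train$individual_id)
  fit <- run_chain(g_train, ph_train, spec, cfg)
  g_test <- .subset_genotypes(g, test_ids)
  genomic_values(g_test, fit$beta_mean, center = 2 * fit$freqs)
}

.subset_genotypes <- function(g, ids) {
  ids <- as.character(ids)
  miss <- setdiff(ids, g$individual_ids)
  if (length(miss)) stop("ids missing from genotypes: ",
                         paste(head(miss, 3), collapse = ", "))
  genotype_matrix(g$codes[match(ids, g$individual_ids), , drop = FALSE],
                  ids, g$marker_ids)
}

#' Cross-validated model comparison
#'
#' For each replicate and fold, every model is fitted on the training
#' individuals only (allele frequencies, genotype centring and GBLUP
#' variance components all come from the training split), DGVs are
#' predicted for the test individuals, and accuracy and bias are recorded.
#' Results are aggregated as mean and standard error over the replicate
#' means (not over all folds).
#'
#' @param g a [genotype_matrix()] covering all phenotyped individuals.
#' @param ph a [phenotype_table()]; rows with `NA` response are dropped.
#' @param models named list of [model_spec()]s.
#' @param cfg a [chain_config()] used for the Gibbs families.
#' @param k,reps,seed fold scheme passed to [make_cv_folds()]; per-fold
#'   chains use `seed` offsets so every fit is reproducible.
#' @return object of class `cv_result`: `$folds` (model, replicate, fold,
#'   accuracy, bias) and `$summary` (per model: accuracy_mean, accuracy_se,
#'   bias_mean, bias_se).
#' @export
cross_validate <- function(g, ph, models, cfg = chain_config(fast = TRUE),
                           k = 6L, reps = 5L, seed = 1L) {
  ph <- ph[!is.na(ph$y), , drop = FALSE]
  class(ph) <- c("phenotype_table", "data.frame")
  ids <- intersect(g$individual_ids, ph$individual_id)
  if (length(ids) < 3L * k) stop("too few phenotyped individuals for ", k,
                                 " folds (need >= 3 per fold)")
  ph <- ph[match(ids, ph$individual_id), , drop = FALSE]
  if (is.null(names(models)))
    names(models) <- vapply(models, `[[`, "", "family")
  folds <- make_cv_folds(length(ids), k, reps, seed)
  has_rel <- !all(is.na(ph$reliability))
  rows <- list()
  for (r in seq_len(reps)) {
    fr <- folds[[r]]
    for (f in seq_len(k)) {
      test <- which(fr == f)
      if (length(test) < 3L) stop("fold with fewer than 3 test individuals")
      train <- which(fr != f)
      ph_train <- ph[train, , drop = FALSE]
      class(ph_train) <- c("phenotype_table", "data.frame")
      for (mn in names(models)) {
        cfg_f <- cfg
        cfg_f$seed <- as.integer((seed + 7L * r + 131L * f) %% .Machine$integer.max)
        dgv <- .fit_predict(g, ph_train, ids[test], models[[mn]], cfg_f)
        rows[[length(rows) + 1L]] <- data.frame(
          model = mn, replicate = r, fold = f,
          accuracy = accuracy(ph$y[test], dgv,
                              if (has_rel) ph$reliability[test] else NULL),
          bias = bias(ph$y[test], dgv),
          stringsAsFactors = FALSE)
      }
    }
  }
  folds_df <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(folds_df, folds_df$model), function(d) {
    rep_acc <- tapply(d$accuracy, d$replicate, mean)
    rep_bias <- tapply(d$bias, d$replicate, mean)
    data.frame(model = d$model[1],
               accuracy_mean = mean(rep_acc),
               accuracy_se = if (length(rep_acc) > 1)
                 sd(rep_acc) / sqrt(length(rep_acc)) else NA_real_,
               bias_mean = mean(rep_bias),
               bias_se = if (length(rep_bias) > 1)
                 sd(rep_bias) / sqrt(length(rep_bias)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(folds = folds_df, summary = summ,
                 k = k, reps = reps, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cross-validation (", x$reps, " x ", x$k, "-fold):\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a CV result as tidy CSVs
#' @param cv a `cv_result`.
#' @param path base path; writes `<path>` (per-fold rows) and
#'   `<path>` with `_summary` inserted before the extension.
#' @return `path`, invisibly.
#' @export
write_cv_csv <- function(cv, path) {
  data.table::fwrite(cv$folds, path, quote = FALSE)
  data.table::fwrite(cv$summary, sub("(\\.csv)?$", "_summary.csv", path),
                     quote = FALSE)
  invisible(path)
}
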