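# Genotype / phenotype IO and quality control.
#
# Additive coding convention: a genotype code is the count (0/1/2) of the
# "counted" allele -- the ALT allele for VCF input, the A1 allele for PLINK
# .raw input, and whatever allele the file's author counted for plain CSV.
# Allele frequencies p_k always refer to the counted allele and are computed
# from non-missing entries only.

#' Construct a genotype matrix
#'
#' The central genotype container: an individuals-by-markers matrix of
#' additive codes in \{0, 1, 2\} (NA marks a missing genotype) together with
#' the counted-allele frequencies `p_k`, computed from non-missing codes.
#'
#' @param codes numeric matrix, individuals in rows, markers in columns;
#'   entries in \{0, 1, 2\} or NA.
#' @param individual_ids character vector of unique row identifiers.
#' @param marker_ids character vector of unique column identifiers.
#' @return an object of class `genotype_matrix` with fields `codes`,
#'   `individual_ids`, `marker_ids`, `freqs`.
#' @export
genotype_matrix <- function(codes, individual_ids = rownames(codes),
                            marker_ids = colnames(codes)) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "double"
  n <- nrow(codes); m <- ncol(codes)
  if (n < 2L) stop("genotype matrix needs at least 2 individuals")
  if (m < 1L) stop("genotype matrix needs at least 1 marker")
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(n))
  if (is.null(marker_ids)) marker_ids <- paste0("snp", seq_len(m))
  individual_ids <- as.character(individual_ids)
  marker_ids <- as.character(marker_ids)
  if (anyDuplicated(individual_ids)) stop("individual ids must be unique")
  if (anyDuplicated(marker_ids)) stop("marker ids must be unique")
  if (length(individual_ids) != n || length(marker_ids) != m)
    stop("id lengths do not match matrix dimensions")
  bad <- !is.na(codes) & !(codes %in% c(0, 1, 2))
  if (any(bad))
    stop("non-missing genotype codes must be 0, 1 or 2 (first offender row ",
         which(bad, arr.ind = TRUE)[1, 1], ")")
  dimnames(codes) <- list(individual_ids, marker_ids)
  structure(
    list(codes = codes,
         individual_ids = individual_ids,
         marker_ids = marker_ids,
         freqs = colMeans(codes, na.rm = TRUE) / 2),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$individual_ids), "individuals x",
      length(x$marker_ids), "markers;",
      sum(is.na(x$codes)), "missing codes\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Read a genotype file
#'
#' Reads additive genotype codes from one of three dialects:
#' \describe{
#'   \item{`csv`}{first column individual id, remaining columns one marker
#'     each, header row carries marker ids; empty cells or NA are missing.}
#'   \item{`plink_raw`}{PLINK `--recode A` output: header
#'     `FID IID PAT MAT SEX PHENOTYPE SNP1_A ...`; codes count the A1 allele;
#'     `NA` marks a missing genotype.}
#'   \item{`vcf`}{a VCF of biallelic SNPs; codes count ALT alleles from the GT
#'     field. Records that are not biallelic SNPs are skipped with a warning.}
#' }
#'
#' @param path file path.
#' @param format one of `"csv"`, `"plink_raw"`, `"vcf"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("csv", "plink_raw", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  switch(format,
    csv = .read_genotypes_csv(path),
    plink_raw = .read_genotypes_raw(path),
    vcf = .read_genotypes_vcf(path))
}

.read_genotypes_csv <- function(path) {
  dt <- tryCatch(
    data.table::fread(path, header = TRUE, na.strings = c("NA", "", ".")),
    error = function(e) stop("failed to parse genotype CSV ", path, ": ",
                             conditionMessage(e)))
  if (ncol(dt) < 2L) stop("genotype CSV needs an id column plus markers")
  ids <- as.character(dt[[1L]])
  codes <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(codes) <- "double"
  genotype_matrix(codes, ids, colnames(dt)[-1L])
}

.read_genotypes_raw <- function(path) {
  dt <- tryCatch(
    data.table::fread(path, header = TRUE, na.strings = c("NA", "")),
    error = function(e) stop("failed to parse PLINK raw file ", path, ": ",
                             conditionMessage(e)))
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(fixed %in% names(dt)[seq_len(6L)]))
    stop("not a PLINK .raw header (expected FID IID PAT MAT SEX PHENOTYPE) in ",
         path)
  ids <- as.character(dt[["IID"]])
  codes <- as.matrix(dt[, -seq_len(6L), drop = FALSE])
  storage.mode(codes) <- "double"
  genotype_matrix(codes, ids, sub("_[ACGT0-9]+$", "", colnames(codes)))
}

.read_genotypes_vcf <- function(path) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF ", path, ": ",
                             conditionMessage(e)))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  biallelic_snp <- !is.na(alt) & !grepl(",", alt) &
    nchar(ref) == 1L & nchar(alt) == 1L
  n_skipped <- sum(!biallelic_snp)
  if (n_skipped > 0L)
    warning(n_skipped, " non-biallelic-SNP record(s) skipped in ", path)
  if (!any(biallelic_snp)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")[biallelic_snp, , drop = FALSE]
  ids <- colnames(gt)
  mk <- fix[biallelic_snp, "ID"]
  noid <- is.na(mk) | mk == "."
  mk[noid] <- paste0(fix[biallelic_snp, "CHROM"], ":",
                     fix[biallelic_snp, "POS"])[noid]
  # count ALT alleles; tolerate phased separators and haploid calls
  count_alt <- function(s) {
    if (is.na(s)) return(NA_real_)
    al <- strsplit(gsub("\\|", "/", s), "/", fixed = TRUE)[[1L]]
    if (any(al == "." | al == "")) return(NA_real_)
    sum(al != "0")
  }
  codes <- t(apply(gt, c(1, 2), count_alt))
  g <- genotype_matrix(codes, ids, mk)
  attr(g, "n_skipped_records") <- n_skipped
  g
}

#' Write genotype codes as CSV
#'
#' Inverse of `read_genotypes(format = "csv")`: id column + one column per
#' marker; missing codes written as NA.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_csv <- function(g, path) {
  dt <- data.table::data.table(id = g$individual_ids)
  dt <- cbind(dt, data.table::as.data.table(g$codes))
  data.table::fwrite(dt, path, na = "NA", quote = FALSE)
  invisible(path)
}

# one-df chi-square HWE test per marker column; returns p-values
hwe_pvalues <- function(codes) {
  apply(codes, 2L, function(x) {
    x <- x[!is.na(x)]
    n <- length(x)
    if (n == 0L) return(NA_real_)
    n2 <- sum(x == 2); n1 <- sum(x == 1); n0 <- n - n1 - n2
    p <- (2 * n2 + n1) / (2 * n)
    if (p <= 0 || p >= 1) return(NA_real_)  # monomorphic: handled by MAF rule
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    chi2 <- sum((c(n0, n1, n2) - e)^2 / e)
    pchisq(chi2, df = 1, lower.tail = FALSE)
  })
}

#' Quality-control filter for genotype data
#'
#' Applies the standard pre-analysis filters: individuals with a fraction of
#' non-missing genotypes below `call_rate_min` are removed first; marker
#' statistics are then recomputed on the retained individuals and markers are
#' removed when the minor allele frequency is below `maf_min` or the
#' one-degree-of-freedom chi-square Hardy-Weinberg test (no continuity
#' correction) gives p below `hwe_alpha`. Monomorphic markers are always
#' removed. Defaults are MAF < 0.01, HWE p < 1e-6, call rate < 0.90.
#'
#' The filter is idempotent: re-applying it to its own output changes nothing.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency to keep a marker.
#' @param hwe_alpha HWE p-value threshold below which a marker is dropped.
#' @param call_rate_min minimum per-individual call rate.
#' @return list with elements `genotypes` (filtered [genotype_matrix()]) and
#'   `report` (a `qc_report`).
#' @export
qc_filter <- function(g, maf_min = 0.01, hwe_alpha = 1e-6,
                      call_rate_min = 0.90) {
  stopifnot(maf_min >= 0, maf_min <= 1, hwe_alpha >= 0, hwe_alpha <= 1,
            call_rate_min >= 0, call_rate_min <= 1)
  codes <- g$codes
  call_rate <- rowMeans(!is.na(codes))
  keep_ind <- call_rate >= call_rate_min
  n_ind_removed <- sum(!keep_ind)
  if (sum(keep_ind) < 2L)
    stop("fewer than 2 individuals pass the call-rate filter")
  codes <- codes[keep_ind, , drop = FALSE]

  p <- colMeans(codes, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  maf <- pmin(p, 1 - p)
  mono <- is.na(maf) | maf == 0
  fail_maf <- !mono & maf < maf_min
  hwe_p <- hwe_pvalues(codes)
  fail_hwe <- !mono & !fail_maf & !is.na(hwe_p) & hwe_p < hwe_alpha
  keep_mk <- !(mono | fail_maf | fail_hwe)
  if (!any(keep_mk))
    stop("quality control removed every marker; relax the thresholds")
  out <- genotype_matrix(codes[, keep_mk, drop = FALSE],
                         g$individual_ids[keep_ind],
                         g$marker_ids[keep_mk])
  report <- structure(
    list(n_individuals_removed = n_ind_removed,
         n_markers_monomorphic = sum(mono),
         n_markers_maf = sum(fail_maf),
         n_markers_hwe = sum(fail_hwe),
         n_individuals_kept = length(out$individual_ids),
         n_markers_kept = length(out$marker_ids),
         thresholds = list(maf_min = maf_min, hwe_alpha = hwe_alpha,
                           call_rate_min = call_rate_min)),
    class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report: removed", x$n_individuals_removed, "individuals (call rate),",
      x$n_markers_monomorphic, "monomorphic,", x$n_markers_maf, "MAF,",
      x$n_markers_hwe, "HWE markers; kept",
      x$n_individuals_kept, "x", x$n_markers_kept, "\n")
  invisible(x)
}

#' Serialize a QC report to JSON
#' @param report a `qc_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Mean-impute missing genotypes
#'
#' Replaces each missing code in column k by twice the counted-allele
#' frequency `2 p_k` computed from the non-missing entries of that column
#' (the column mean), leaving observed codes untouched.
#'
#' @param g a [genotype_matrix()].
#' @return a [genotype_matrix()] without missing entries. The imputed matrix
#'   no longer has integer codes in the filled cells.
#' @export
impute_missing_mean <- function(g) {
  codes <- g$codes
  miss <- is.na(codes)
  if (!any(miss)) return(g)
  all_missing <- colSums(!miss) == 0L
  if (any(all_missing))
    stop("column(s) entirely missing, frequency undefined: ",
         paste(g$marker_ids[all_missing], collapse = ", "))
  fill <- 2 * g$freqs
  idx <- which(miss, arr.ind = TRUE)
  codes[miss] <- fill[idx[, 2L]]
  out <- g
  out$codes <- codes
  out$freqs <- colMeans(codes) / 2
  out
}

#' Construct a phenotype table
#'
#' Holds the per-individual response `y` (a phenotype, pre-corrected
#' phenotype, or de-regressed proof), an optional reliability `r2` per record
#' and the residual weight `d_ii` of the diagonal residual covariance
#' `D * sigma2_e`. With reliabilities, `d_ii = (1 - r2)/r2`, which inflates
#' residual variance for low-reliability records; without them `d_ii = 1`.
#'
#' @param individual_ids character ids.
#' @param y numeric response.
#' @param reliability optional per-record reliability in (0, 1].
#' @return data.frame of class `phenotype_table` with columns
#'   `individual_id`, `y`, `reliability`, `weight`.
#' @export
phenotype_table <- function(individual_ids, y, reliability = NULL) {
  individual_ids <- as.character(individual_ids)
  stopifnot(length(individual_ids) == length(y))
  if (anyDuplicated(individual_ids)) stop("individual ids must be unique")
  if (is.null(reliability)) {
    w <- rep(1, length(y))
    reliability <- rep(NA_real_, length(y))
  } else {
    stopifnot(length(reliability) == length(y))
    bad <- !is.na(reliability) & (reliability <= 0 | reliability > 1)
    if (any(bad))
      stop("reliability outside (0, 1] for id(s): ",
           paste(individual_ids[bad], collapse = ", "))
    w <- ifelse(is.na(reliability), 1, (1 - reliability) / reliability)
    # r2 = 1 gives a zero residual weight; floor keeps D invertible
    w <- pmax(w, 1e-8)
  }
  structure(
    data.frame(individual_id = individual_ids, y = as.numeric(y),
               reliability = reliability, weight = w,
               stringsAsFactors = FALSE),
    class = c("phenotype_table", "data.frame"))
}

#' Read a phenotype / DRP table
#'
#' Expects a CSV/TSV with columns `id` and `y`, plus either a `reliability`
#' column (DRP reliabilities r2 in (0, 1]) or an `erc` column of effective
#' record contributions. With `erc` and a heritability `h2`, reliabilities
#' are derived as `ERC/(ERC + lambda)`, `lambda = (1-h2)/h2` (see
#' [drp_reliability()]). Records with a reliability outside (0, 1] are
#' rejected with a message. Residual weights follow [phenotype_table()].
#'
#' @param path file path.
#' @param h2 trait heritability, needed only to convert an `erc` column.
#' @return a [phenotype_table()].
#' @export
read_phenotypes <- function(path, h2 = NULL) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  dt <- data.table::fread(path, header = TRUE)
  names(dt) <- tolower(names(dt))
  if (!all(c("id", "y") %in% names(dt)))
    stop("phenotype table needs columns 'id' and 'y'")
  rel <- NULL
  if ("reliability" %in% names(dt)) {
    rel <- as.numeric(dt[["reliability"]])
  } else if ("erc" %in% names(dt)) {
    if (is.null(h2)) stop("an 'erc' column needs h2 to derive reliabilities")
    rel <- drp_reliability(as.numeric(dt[["erc"]]), h2)
  }
  if (!is.null(rel)) {
    bad <- !is.na(rel) & (rel <= 0 | rel > 1)
    if (any(bad)) {
      message(sum(bad), " record(s) rejected: reliability outside (0, 1]")
      dt <- dt[!bad, ]; rel <- rel[!bad]
    }
  }
  yv <- as.numeric(dt[["y"]])
  if (anyNA(yv)) {
    message(sum(is.na(yv)), " record(s) without a response dropped")
    keep <- !is.na(yv)
    dt <- dt[keep, ]; yv <- yv[keep]
    if (!is.null(rel)) rel <- rel[keep]
  }
  phenotype_table(dt[["id"]], yv, rel)
}

#' Write a phenotype table as CSV
#' @param ph a [phenotype_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes_csv <- function(ph, path) {
  data.table::fwrite(
    data.table::data.table(id = ph$individual_id, y = ph$y,
                           reliability = ph$reliability),
    path, na = "NA", quote = FALSE)
  invisible(path)
}
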