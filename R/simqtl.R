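# Synthetic pedigree / genotype / phenotype generator emulating the
# 15th QTL-MAS workshop design: 20 founder sires each mated to 10 dams,
# 15 offspring per dam, five chromosomes of SNPs with founder LD, few QTL,
# residuals scaled to hit a target realized heritability, and DRP-like
# records with assigned reliabilities.

#' Simulation configuration
#'
#' Defaults mirror the QTL-MAS-style design: 20 sires x 10 dams each x 15
#' offspring (3000 offspring), five chromosomes, 8 additive QTL and a target
#' realized heritability of 0.3. One third of each family carries genotypes
#' but no phenotype.
#'
#' @param n_sires,dams_per_sire,offspring_per_dam pedigree counts.
#' @param n_chrom,snps_per_chrom marker layout; each chromosome spans 1
#'   Morgan with evenly spaced markers.
#' @param n_qtl number of causal markers.
#' @param h2 target realized heritability in (0, 1).
#' @param ld_decay founder-haplotype correlation scale in Morgans: the
#'   latent correlation between markers at distance d is `exp(-d/ld_decay)`.
#'   0 gives independent founder alleles.
#' @param qtl_effect_dist `"gaussian"` or `"gamma"` (gamma effects get a
#'   random sign).
#' @param epistasis optional fraction of QTL pairs given an extra product
#'   interaction term (0 disables).
#' @param prop_genotyped_only fraction of offspring with genotype but no
#'   phenotype.
#' @param seed RNG seed used by the generator wrappers.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_sires = 20L, dams_per_sire = 10L,
                       offspring_per_dam = 15L, n_chrom = 5L,
                       snps_per_chrom = 1400L, n_qtl = 8L, h2 = 0.3,
                       ld_decay = 0.05, qtl_effect_dist = c("gaussian", "gamma"),
                       epistasis = 0, prop_genotyped_only = 1 / 3,
                       seed = 1L) {
  qtl_effect_dist <- match.arg(qtl_effect_dist)
  stopifnot(n_sires >= 1, dams_per_sire >= 1, offspring_per_dam >= 1,
            n_chrom >= 1, snps_per_chrom >= 1, n_qtl >= 1,
            h2 > 0, h2 < 1, ld_decay >= 0, epistasis >= 0, epistasis <= 1,
            prop_genotyped_only >= 0, prop_genotyped_only < 1)
  structure(list(n_sires = as.integer(n_sires),
                 dams_per_sire = as.integer(dams_per_sire),
                 offspring_per_dam = as.integer(offspring_per_dam),
                 n_chrom = as.integer(n_chrom),
                 snps_per_chrom = as.integer(snps_per_chrom),
                 n_qtl = as.integer(n_qtl), h2 = h2, ld_decay = ld_decay,
                 qtl_effect_dist = qtl_effect_dist, epistasis = epistasis,
                 prop_genotyped_only = prop_genotyped_only,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate the mating pedigree
#'
#' Founder sires and dams plus full-sib families: each sire is mated to
#' `dams_per_sire` dams and each dam produces `offspring_per_dam` offspring.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with columns `id`, `sire`, `dam` (NA for founders),
#'   `generation` (0 founders, 1 offspring), `sex`.
#' @export
simulate_pedigree <- function(cfg) {
  n_dams <- cfg$n_sires * cfg$dams_per_sire
  sires <- sprintf("S%03d", seq_len(cfg$n_sires))
  dams <- sprintf("D%04d", seq_len(n_dams))
  off_sire <- rep(sires, each = cfg$dams_per_sire * cfg$offspring_per_dam)
  off_dam <- rep(dams, each = cfg$offspring_per_dam)
  n_off <- length(off_dam)
  off <- sprintf("O%05d", seq_len(n_off))
  data.frame(
    id = c(sires, dams, off),
    sire = c(rep(NA_character_, cfg$n_sires + n_dams), off_sire),
    dam = c(rep(NA_character_, cfg$n_sires + n_dams), off_dam),
    generation = c(rep(0L, cfg$n_sires + n_dams), rep(1L, n_off)),
    sex = c(rep("M", cfg$n_sires), rep("F", n_dams),
            sample(c("M", "F"), n_off, replace = TRUE)),
    stringsAsFactors = FALSE)
}

# founder haplotype block: latent AR(1) Gaussian thresholded at the marker's
# allele frequency, giving spatially correlated 0/1 alleles
.founder_haplotypes <- function(n_hap, pos, p, ld_decay) {
  m <- length(pos)
  H <- matrix(0L, n_hap, m)
  rho <- if (ld_decay <= 0) rep(0, max(m - 1L, 0L))
         else exp(-diff(pos) / ld_decay)
  for (h in seq_len(n_hap)) {
    z <- numeric(m)
    z[1] <- rnorm(1)
    if (m > 1L) {
      eps <- rnorm(m - 1L)
      for (j in 2:m) z[j] <- rho[j - 1L] * z[j - 1L] +
          sqrt(1 - rho[j - 1L]^2) * eps[j - 1L]
    }
    H[h, ] <- as.integer(z < qnorm(p))
  }
  H
}

# recombine two parental haplotypes along one chromosome: crossover count
# Poisson(length in Morgans), positions uniform, random starting phase
.meiosis <- function(hap1, hap2, pos) {
  L <- pos[length(pos)] - pos[1]
  n_x <- rpois(1, max(L, 0))
  cur <- sample(0:1, 1L)
  if (n_x == 0L) return(if (cur == 0L) hap1 else hap2)
  xpos <- sort(runif(n_x, pos[1], pos[length(pos)]))
  seg <- findInterval(pos, xpos)   # number of crossovers to the left
  use2 <- (seg + cur) %% 2L == 1L
  out <- hap1
  out[use2] <- hap2[use2]
  out
}

#' Simulate genotypes by gene dropping
#'
#' Founder haplotypes are drawn with spatially correlated allele states
#' (latent AR(1), correlation `exp(-d/ld_decay)` at map distance d, founder
#' frequencies uniform on (0.1, 0.9)); offspring receive recombination-aware
#' gametes from their parents, with Poisson crossovers along each 1-Morgan
#' chromosome. Returns additive 0/1/2 codes for every pedigree member.
#'
#' @param pedigree output of [simulate_pedigree()].
#' @param cfg a [sim_config()].
#' @return a [genotype_matrix()]; marker ids `c<chrom>_snp<index>`. The map
#'   positions (Morgans) are attached as attribute `"map"`.
#' @export
simulate_genotypes <- function(pedigree, cfg) {
  m_chr <- cfg$snps_per_chrom
  pos1 <- seq(0, 1, length.out = m_chr + 1L)[-1L]
  n_ind <- nrow(pedigree)
  founder <- is.na(pedigree$sire)
  idx <- setNames(seq_len(n_ind), pedigree$id)
  m_tot <- cfg$n_chrom * m_chr
  codes <- matrix(0, n_ind, m_tot)
  map <- data.frame(chrom = rep(seq_len(cfg$n_chrom), each = m_chr),
                    pos = rep(pos1, cfg$n_chrom))
  for (chr in seq_len(cfg$n_chrom)) {
    cols <- (chr - 1L) * m_chr + seq_len(m_chr)
    p <- runif(m_chr, 0.1, 0.9)
    H1 <- matrix(0L, n_ind, m_chr)  # paternal haplotype per individual
    H2 <- matrix(0L, n_ind, m_chr)  # maternal haplotype
    nf <- sum(founder)
    FH <- .founder_haplotypes(2L * nf, pos1, p, cfg$ld_decay)
    H1[founder, ] <- FH[seq_len(nf) * 2L - 1L, , drop = FALSE]
    H2[founder, ] <- FH[seq_len(nf) * 2L, , drop = FALSE]
    for (i in which(!founder)) {
      si <- idx[[pedigree$sire[i]]]
      di <- idx[[pedigree$dam[i]]]
      H1[i, ] <- .meiosis(H1[si, ], H2[si, ], pos1)
      H2[i, ] <- .meiosis(H1[di, ], H2[di, ], pos1)
    }
    codes[, cols] <- H1 + H2
  }
  colnames(codes) <- paste0("c", map$chrom, "_snp",
                            rep(seq_len(m_chr), cfg$n_chrom))
  g <- genotype_matrix(codes, pedigree$id, colnames(codes))
  attr(g, "map") <- map
  g
}

#' Simulate phenotypes with a sparse QTL architecture
#'
#' Chooses `n_qtl` polymorphic markers as causal loci, draws their additive
#' effects from `qtl_effect_dist`, optionally adds pairwise product
#' epistasis, and then scales residuals so the realized (sample)
#' heritability `var(gv)/var(y)` hits the target exactly: the residual draw
#' is orthogonalised against the genetic values and rescaled, matching the
#' "realized heritability" convention.
#'
#' @param g a [genotype_matrix()].
#' @param cfg a [sim_config()].
#' @return list with `phenotypes` (a [phenotype_table()]; individuals drawn
#'   as genotype-only get `y = NA`) and `truth` (class `sim_truth`:
#'   `true_beta`, `true_gv`, `qtl_idx`, `realized_h2`).
#' @export
simulate_phenotypes <- function(g, cfg) {
  m <- ncol(g$codes); n <- nrow(g$codes)
  if (cfg$n_qtl > m) stop("more QTL requested than markers available")
  poly <- which(g$freqs > 0 & g$freqs < 1)
  for (attempt in seq_len(100L)) {
    qtl <- sort(sample(poly, cfg$n_qtl))
    eff <- switch(cfg$qtl_effect_dist,
      gaussian = rnorm(cfg$n_qtl),
      gamma = rgamma(cfg$n_qtl, shape = 0.4, rate = 1.66) *
        sample(c(-1, 1), cfg$n_qtl, replace = TRUE))
    gv <- drop(g$codes[, qtl, drop = FALSE] %*% eff)
    if (cfg$epistasis > 0 && cfg$n_qtl >= 2L) {
      n_pairs <- max(1L, floor(cfg$epistasis * cfg$n_qtl / 2))
      pr <- matrix(sample(qtl, 2L * n_pairs, replace = FALSE), ncol = 2L)
      for (j in seq_len(n_pairs))
        gv <- gv + rnorm(1, 0, sd(eff)) *
          g$codes[, pr[j, 1L]] * g$codes[, pr[j, 2L]]
    }
    if (var(gv) > 0) break
    if (attempt == 100L) stop("all sampled QTL monomorphic after 100 attempts")
  }
  e0 <- rnorm(n)
  e0 <- e0 - mean(e0)
  e0 <- e0 - gv * (sum(e0 * (gv - mean(gv))) / sum((gv - mean(gv))^2))
  e <- e0 * sqrt(var(gv) * (1 - cfg$h2) / cfg$h2 / var(e0))
  y <- gv + e
  true_beta <- numeric(m)
  true_beta[qtl] <- eff
  y_obs <- y
  if (cfg$prop_genotyped_only > 0) {
    n_hide <- floor(cfg$prop_genotyped_only * n)
    hide <- sample(n, n_hide)
    y_obs[hide] <- NA_real_
  }
  ph <- phenotype_table(g$individual_ids, y_obs)
  truth <- structure(
    list(true_beta = true_beta, true_gv = gv, qtl_idx = qtl,
         qtl_ids = g$marker_ids[qtl],
         realized_h2 = var(gv) / var(y)),
    class = "sim_truth")
  list(phenotypes = ph, truth = truth)
}

#' Simulate DRP-like records from true genetic values
#'
#' Emulates de-regressed proofs: each individual gets a reliability r2 drawn
#' uniformly in `reliability_range`; its DRP is the true genetic value plus
#' noise of variance `var(gv) (1 - r2)/r2`, so that the squared correlation
#' of DRP with gv approaches r2 in expectation. Residual weights are
#' `d_ii = (1 - r2)/r2` as in [phenotype_table()].
#'
#' @param truth a `sim_truth` from [simulate_phenotypes()].
#' @param individual_ids ids matching `truth$true_gv`.
#' @param reliability_range length-2 interval inside (0, 1).
#' @return a [phenotype_table()] with `y` = DRP and the drawn reliabilities.
#' @export
simulate_drp <- function(truth, individual_ids,
                         reliability_range = c(0.4, 0.9)) {
  stopifnot(length(reliability_range) == 2,
            reliability_range[1] > 0, reliability_range[2] < 1,
            reliability_range[1] <= reliability_range[2])
  gv <- truth$true_gv
  stopifnot(length(individual_ids) == length(gv))
  r2 <- runif(length(gv), reliability_range[1], reliability_range[2])
  drp <- gv + rnorm(length(gv), 0, sqrt(var(gv) * (1 - r2) / r2))
  phenotype_table(individual_ids, drp, r2)
}

#' One-call QTL-MAS-style dataset
#'
#' Runs [simulate_pedigree()], [simulate_genotypes()] and
#' [simulate_phenotypes()] under `cfg$seed` and returns everything.
#'
#' @param cfg a [sim_config()].
#' @return list with `pedigree`, `genotypes`, `phenotypes`, `truth`.
#' @export
simulate_qtlmas <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  sim <- simulate_phenotypes(g, cfg)
  list(pedigree = ped, genotypes = g, phenotypes = sim$phenotypes,
       truth = sim$truth)
}
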