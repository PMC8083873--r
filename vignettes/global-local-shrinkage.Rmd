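---
title: "Genomic prediction with global-local shrinkage priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction with global-local shrinkage priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

All Bayesian families in `bayesgl` fit the same whole-genome regression

$$ y = \mu \mathbf{1} + \sum_{k=1}^{m} x_k \beta_k + e, \qquad
   e \sim N(0, D\sigma_e^2), $$

where $y$ is a phenotype, a pre-corrected phenotype or a de-regressed proof
(DRP), $x_k$ is the additive genotype code of SNP $k$ (0/1/2, centred by
$2p_k$ before sampling), and $D$ is diagonal. With DRPs,
$d_{ii} = (1-r_i^2)/r_i^2$ down-weights records with low reliability
$r_i^2$; with ordinary phenotypes $D = I$.

The families differ only in the prior on $\beta_k$:

* **BayesU** (Horseshoe): $\beta_k \sim N(0, \lambda_k^2\tau^2)$,
  $\lambda_k \sim C^+(0,1)$, flat prior on $\tau$.
* **BayesHP** (Horseshoe+): a second local layer,
  $\lambda_k \sim C^+(0,\eta_k)$, $\eta_k \sim C^+(0,1)$, and a proper
  global prior $\tau \sim C^+(0, 1/N)$ with $N$ the training size.
* **BayesHE**: $\lambda_k \sim \text{half-}t(\upsilon, 1)$ with the degrees
  of freedom *unknown*, $\upsilon \sim \Gamma(a,b)$, sampled by a
  random-walk Metropolis-Hastings step on $\zeta = \log\upsilon$. The
  presets $a=4,b=1$ ("HE1") and $a=5,b=1$ ("HE2") give prior means 4 and 5.
* **BayesA / BayesB**: scaled-$t$ effects via per-marker variances
  $\sigma^2_{\beta,k} \sim \text{IG}(\nu/2, \nu S_\beta^2/2)$; BayesB
  multiplies a point mass at zero with probability $\pi$ (default 0.95),
  sampled by a collapsed (effect-integrated) indicator update. BayesA is
  the $\pi = 0$ special case.
* **GBLUP**: $y = \mu\mathbf{1} + g + e$, $g \sim N(0, G\sigma_g^2)$ with
  the VanRaden relationship matrix
  $G = (M-P)(M-P)'/(2\sum_k p_k(1-p_k))$; variance components by EM-REML.

Every half-Cauchy and half-$t$ scale is handled through the inverse-gamma
mixture: if $x^2 \sim \text{IG}(\tfrac12, 1/a)$ and
$a \sim \text{IG}(\tfrac12, 1/A^2)$ then $x \sim C^+(0, A)$. All
conditionals then stay inverse-gamma and the whole sampler is Gibbs, except
for the single scalar MH step for $\upsilon$. The package-wide convention
is $\text{IG}(\alpha,\gamma)$ with density
$\propto x^{-\alpha-1}e^{-\gamma/x}$; every conditional in the code is
stated in this convention and checked against a numeric grid oracle in the
test suite.

## Priors the hierarchy leaves open

The intercept gets a flat prior and the residual variance the scale-uniform
Jeffreys prior $\propto 1/\sigma_e^2$; both conditionals stay conjugate.
(`model_spec()` also accepts proper normal / inverse-gamma settings, which
the joint-distribution validation tests use, since improper priors cannot
be sampled from.) The flat BayesU global prior is interpreted as flat on
$\tau$ (not $\tau^2$), so the $\tau^2$ conditional carries the
$(\tau^2)^{-1/2}$ transform factor and needs $m \ge 2$. For BayesA/B the
$t$ scale defaults to
$S_\beta^2 = h^2_{\text{prior}} \mathrm{var}(y)(\nu-2) /
(\nu \sum_k 2p_k(1-p_k))$ with $\nu = 4.2$ and
$h^2_{\text{prior}} = 0.5$, i.e. the prior total marker variance is half
the phenotypic variance; both are exposed in `model_spec()`.

## Chain control and numerics

`chain_config()` defaults to 50,000 sweeps, 20,000 burn-in, thinning 50
(600 saved draws); `fast = TRUE` gives the desk-scale preset
5,000/2,000/10 used throughout the tests. One sweep updates, in fixed
order: $\mu$, the marker loop over $\beta_k$ (compiled; the residual vector
is updated incrementally in $O(n)$ per marker and a test confirms the
compiled path draws bit-identically to the R reference updates), the local
scales (vectorised over markers), the global scales $(\tau^2, \xi)$,
$\upsilon$ (BayesHE), and $\sigma_e^2$. Saved draws record $\mu$ and the
additive variance $V_g = \mathrm{var}(\sum_k x_k\beta_k)$ (denominator
$n-1$), recovered in $O(n)$ from the residual identity.

Numerical guards: inverse-gamma rates are floored at $10^{-300}$,
$\lambda_k^2$ is clamped to $[10^{-12}, 10^{12}]$ (horseshoe tails
overflow doubles), and $\upsilon$ is restricted to $[0.05, 200]$ where
$\Gamma(\upsilon/2)$ is representable. The MH step size (default 0.5 on the
log scale) is Robbins-Monro adapted toward 0.44 acceptance during burn-in
only, so the post-burn-in kernel is fixed and the stationary law untouched.
DGVs exclude the intercept: the accuracy and bias metrics are
location-invariant, and this keeps DGVs comparable across models.

## Data handling choices

Additive codes count the ALT allele (VCF) or the A1 allele (PLINK `.raw`).
QC removes low-call-rate individuals first, then recomputes marker
statistics and drops markers by MAF < 0.01, a one-df chi-square
Hardy-Weinberg test at $p < 10^{-6}$ (no continuity correction), and
monomorphism; the individual-before-marker order is a fixed, documented
choice. QC runs before imputation, and the built-in imputation is
column-mean ($2p_k$) substitution; haplotype-based imputation is out of
scope. Reliabilities of exactly 1 would give a zero residual weight, so
weights are floored at $10^{-8}$.

## What the simulator emulates

`simulate_qtlmas()` mirrors a QTL-MAS-workshop-style design: 20 founder
sires each mated to 10 dams, 15 offspring per dam (3,000 offspring), five
1-Morgan chromosomes, 8 QTL, and residuals scaled so the *realized*
(sample) heritability is exactly the target (default 0.3) — the residual
draw is orthogonalised against the genetic values before scaling, matching
the realized-heritability convention rather than an expected-variance one.
Founder LD comes from a latent AR(1) copula with correlation
$e^{-d/\text{ld\_decay}}$ at map distance $d$ (default scale 0.05 Morgans,
which gives strong adjacent-marker LD at 50K-chip-like densities); gene
dropping uses Poisson recombination. One third of individuals carry
genotypes but no phenotype. DRP-like records add noise of variance
$\mathrm{var}(g)(1-r^2)/r^2$ for a drawn reliability $r^2$, so
$\mathrm{cor}^2(\text{DRP}, g) \approx r^2$.

Simplifications relative to the original workshop data: all QTL are
biallelic and additive (optional product-term epistasis behind a flag);
there is no coalescent founder history, no imprinting, and no multi-allelic
locus. Founders are phenotyped like offspring. Passing tests on this
generator therefore demonstrate correct inference under a controlled
additive architecture with family structure and LD — not robustness to the
full complexity of real cattle data (selection, non-additive QTL,
genotyping error).

## Validation design

The test suite validates the sampler itself, not only its outputs:

* every inverse-gamma/normal conditional is compared, as a distribution,
  with a brute-force grid integration of the hierarchy factors (sup CDF
  gap $< 10^{-3}$); the BayesB indicator against direct enumeration;
* the chained IG mixtures are checked to reproduce $C^+(0,A)$ and the
  Horseshoe+ local prior against two-path sampling;
* the $\upsilon$ step recovers its Gamma prior exactly at $m=0$ and the
  quadrature-normalised posterior on a frozen state;
* a joint-distribution (marginal- vs successive-conditional) comparison is
  run per family at $n=10, m=5$ with proper priors. The successive side
  uses many short chains initialised at exact prior draws, so chain means
  are independent unbiased replicates; this sidesteps the very long
  autocorrelation of the global scale at small $m$. For BayesU the flat
  $\tau$ prior cannot be drawn from, so that family is validated with
  $\tau^2$ held fixed, and $\tau^2$ agreement is compared on the log scale
  because the half-Cauchy has no polynomial moments;
* GBLUP is tied to the Bayesian side through the exact GBLUP = SNP-BLUP
  ridge identity at matched variance components, and BayesB at $\pi = 0$
  must reproduce BayesA.

Cross-validation follows the 5 x 6 scheme (six folds, five replicates);
training folds supply allele frequencies, centring and variance
components; the summary reports mean and standard error over the five
replicate means. Accuracy is $\mathrm{cor}(y, \text{DGV})$, divided by
$\bar r$ (mean square-root reliability of the test records) when the
response is a DRP; bias is the regression slope of $y$ on DGV. The
architecture-response checks in the acceptance tests use a sparse
($n=1{,}000$ phenotyped, $m=2{,}000$, 10 QTL, $h^2=0.5$) and a dense
(1,000 causal markers, $h^2=0.3$) simulation with the fast chain preset —
sizes chosen so the whole suite stays a desk-scale run.

## Known limitations

EM-REML is single-random-effect only (no pedigree A or H matrices, single
trait). The GRM is blended with $0.01 I$ by default before solving, which
the exact-equivalence tests switch off. The BayesB $\pi$ is fixed, not
estimated (no BayesC$\pi$). The MH step for $\upsilon$ is a plain random
walk; slice or adaptive alternatives are out of scope.
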