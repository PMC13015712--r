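#' Expected minor allele frequency of a genotype
#'
#' For a genotype with `m` copies of one allele out of `k` total copies the
#' expected minor allele frequency is min(m, k - m) / k: 0 for homozygous
#' genotypes, 1/3 for a 3-copy heterozygote, 1/4 or 1/2 for 4-copy
#' heterozygotes, and so on.
#'
#' @param m integer, copies of the counted allele, 0 <= m <= k.
#' @param k integer copy number, k >= 1.
#' @return expected MAF in \[0, 0.5\].
#' @export
expected_maf <- function(m, k) {
  if (any(k < 1)) stop("copy number k must be >= 1")
  if (any(m < 0) || any(m > k)) stop("allele copies m must satisfy 0 <= m <= k")
  pmin(m, k - m) / k
}

#' Genotype priors for a copy-number state
#'
#' Returns the genotype set for state `k` with prior masses anchored by the
#' per-amplicon heterozygosity rate `h`. For the diploid state:
#' P(AB) = h, P(AA) = P(BB) = (1 - h)/2. For other states the homozygous
#' mass 1 - h is split equally between the two all-one-allele genotypes and
#' the heterozygous mass h is split uniformly over the k - 1 mixed
#' genotypes (m = 1..k-1), the maximum-entropy interpolation that recovers
#' the diploid rule at k = 2. For k = 1 no heterozygote exists and the two
#' monosomic genotypes get mass 1/2 each.
#'
#' @param k copy-number state, 1..5.
#' @param h heterozygosity rate in \[0, 1\].
#' @return data.frame with columns `m` (minor-allele copies), `mass`
#'   (prior, sums to 1), `mu` (expected MAF).
#' @export
genotype_priors <- function(k, h) {
  stopifnot(length(k) == 1L, k >= 1, h >= 0, h <= 1)
  m <- 0:k
  mass <- if (k == 1L) {
    c(0.5, 0.5)
  } else {
    w <- numeric(k + 1L)
    w[c(1L, k + 1L)] <- (1 - h) / 2
    w[2:k] <- h / (k - 1L)
    w
  }
  data.frame(m = m, mass = mass, mu = expected_maf(m, k))
}

# Genotypes sharing an expected MAF are indistinguishable in the likelihood,
# so collapse each state's prior to its unique MAF values. Masses that
# depend on h are expressed as (a + b*h) coefficients so the per-amplicon
# mixture weights can be formed vectorially: mass_i = a + b * h_i.
# Returns, per state k, data.frame(mu, a, b).
maf_mixture_components <- function(K = 5L) {
  lapply(seq_len(K), function(k) {
    pri0 <- genotype_priors(k, 0)
    pri1 <- genotype_priors(k, 1)
    mu <- pri0$mu
    agg0 <- tapply(pri0$mass, mu, sum)
    agg1 <- tapply(pri1$mass, mu, sum)
    u <- as.numeric(names(agg0))
    data.frame(mu = u, a = as.numeric(agg0), b = as.numeric(agg1 - agg0))
  })
}

#' Truncated-normal density for minor allele frequencies
#'
#' Density of a normal with mean `mu_g` (the genotype's expected MAF) and
#' standard deviation `sigma_b`, truncated to the folded frequency range
#' \[0, 0.5\].
#'
#' @param b observed MAF value(s) in \[0, 0.5\].
#' @param mu_g genotype expected MAF.
#' @param sigma_b standard deviation, > 0.
#' @param log return log density.
#' @return density values.
#' @export
truncnorm_maf_density <- function(b, mu_g, sigma_b, log = FALSE) {
  stopifnot(sigma_b > 0)
  if (any(b < 0 | b > 0.5, na.rm = TRUE)) {
    stop("MAF values must lie in [0, 0.5]")
  }
  z <- stats::pnorm(0.5, mu_g, sigma_b) - stats::pnorm(0, mu_g, sigma_b)
  if (any(z <= 0)) stop("degenerate truncation normalizer (sigma too small?)")
  ld <- stats::dnorm(b, mu_g, sigma_b, log = TRUE) - log(z)
  if (log) ld else exp(ld)
}
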