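# Independent oracles and small fixture builders used across test files.

# Exhaustive-path HMM oracle: enumerates all K^n state paths and computes
# the likelihood, state posteriors, transition posteriors, and the most
# probable path directly from the joint probabilities.
bf_hmm <- function(logE, Tm, init = rep(1 / ncol(logE), ncol(logE))) {
  n <- nrow(logE)
  K <- ncol(logE)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  logp <- apply(paths, 1L, function(z) {
    lp <- log(init[z[1L]]) + logE[1L, z[1L]]
    if (n > 1L) {
      for (t in 2:n) lp <- lp + log(Tm[z[t - 1L], z[t]]) + logE[t, z[t]]
    }
    lp
  })
  m <- max(logp)
  w <- exp(logp - m)
  lik <- sum(w)
  gamma <- matrix(0, n, K)
  for (t in seq_len(n)) {
    for (k in seq_len(K)) gamma[t, k] <- sum(w[paths[, t] == k]) / lik
  }
  xi <- if (n > 1L) {
    x <- array(0, c(n - 1L, K, K))
    for (t in 2:n) {
      for (j in seq_len(K)) {
        for (k in seq_len(K)) {
          x[t - 1L, j, k] <-
            sum(w[paths[, t - 1L] == j & paths[, t] == k]) / lik
        }
      }
    }
    x
  }
  list(gamma = gamma, xi = xi, loglik = m + log(lik),
       viterbi = as.integer(paths[which.max(logp), ]))
}

# Random emission/transition instance for oracle comparisons.
random_instance <- function(n, K) {
  logE <- matrix(stats::rnorm(n * K, sd = 2), n, K)
  eps <- stats::runif(1, 0.05, 0.6)
  init <- as.vector(stats::rmultinom(1, 50, rep(1, K))) + 1
  list(logE = logE, Tm = transition_matrix(eps, K), init = init / sum(init))
}

# Small random per-cell observation bundle for EM tests: data drawn from
# the generative model itself (Gaussian depth around k/2, truncated-normal
# MAF around genotype means).
random_cell_obs <- function(n_chr = 6L, amp_per_chr = 4L, vpa = 2L,
                            het = 1, sigma_d = 0.3, sigma_b = 0.07,
                            states = NULL) {
  A <- n_chr * amp_per_chr
  chrom <- rep(as.character(seq_len(n_chr)), each = amp_per_chr)
  if (is.null(states)) {
    states <- rep(sample(c(1L, 2L, 3L), n_chr, replace = TRUE),
                  each = amp_per_chr)
  }
  d <- stats::rnorm(A, states / 2, sigma_d)
  names(d) <- sprintf("a%03d", seq_len(A))
  h <- rep(het, A)
  maf <- numeric(0)
  var_amp <- character(0)
  if (vpa > 0L) {
    for (i in seq_len(A)) {
      pri <- genotype_priors(states[i], het)
      g <- sample(seq_len(nrow(pri)), vpa, replace = TRUE, prob = pri$mass)
      b <- stats::rnorm(vpa, pri$mu[g], sigma_b)
      b <- pmin(pmax(b, 0), 0.5)
      maf <- c(maf, b)
      var_amp <- c(var_amp, rep(names(d)[i], vpa))
    }
  }
  obs <- build_cell_obs(d, maf, var_amp, chrom, h)
  list(obs = obs, states = states, chrom = chrom)
}

# Tiny two-population dataset for fast end-to-end tests.
tiny_sim <- function(seed, n_chromosomes = 8L, cells_per_group = 25L,
                     direction = "gain", ...) {
  build_study2(direction, seed = seed, cells_per_group = cells_per_group,
               n_chromosomes = n_chromosomes, n_altered = 3L, ...)
}

default_params <- function(K = 5L, sigma_d2 = 0.09, sigma_b = 0.07,
                           epsilon = 1e-3) {
  list(mu = seq_len(K) / 2, sigma_d2 = sigma_d2, sigma_b = sigma_b,
       epsilon = epsilon, K = K)
}
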