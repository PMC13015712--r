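#' Copy-number transition matrix
#'
#' Persistence matrix with rare breakpoints: probability 1 - epsilon of
#' staying in the same state between adjacent amplicons, with the switch
#' mass epsilon spread evenly over the K - 1 other states.
#'
#' @param epsilon switch probability, in (0, 1).
#' @param K number of states.
#' @return K x K row-stochastic matrix.
#' @export
transition_matrix <- function(epsilon, K = 5L) {
  if (!(epsilon > 0 && epsilon < 1)) stop("epsilon must lie in (0, 1)")
  if (K < 2L) stop("K must be >= 2")
  Tm <- matrix(epsilon / (K - 1L), K, K)
  diag(Tm) <- 1 - epsilon
  Tm
}

#' Joint depth + allele-frequency emission log-probability
#'
#' Log-probability of one amplicon's observations under copy-number state
#' `k`. The emission factorizes into a Gaussian depth term,
#' N(d | mu\[k\], sigma_d^2), and an allele-frequency term. Each variant's
#' genotype is marginalized independently over the genotypes compatible
#' with state `k`:
#' prod_v sum_g P(g | k, h) p(b_v | g), each MAF observation following a
#' truncated normal on \[0, 0.5\] centered at the genotype's expected MAF.
#' Variants are independent sites, so each carries its own latent
#' genotype; an amplicon may host heterozygous and homozygous variants
#' side by side and the likelihood must not force them onto one shared
#' genotype. A missing depth or an amplicon without variants simply drops
#' the corresponding factor; with both absent the amplicon is
#' uninformative (log-probability 0).
#'
#' @param k copy-number state.
#' @param d normalized depth observation (NA if missing).
#' @param b numeric vector of observed MAF values (possibly empty).
#' @param mu per-state depth means (length >= k).
#' @param sigma_d2 depth variance.
#' @param sigma_b MAF standard deviation.
#' @param h heterozygosity rate of the amplicon.
#' @return log emission probability (scalar).
#' @export
emission_logprob <- function(k, d, b, mu, sigma_d2, sigma_b, h) {
  lp <- 0
  if (!is.na(d)) {
    lp <- lp + stats::dnorm(d, mu[k], sqrt(sigma_d2), log = TRUE)
  }
  b <- b[!is.na(b)]
  if (length(b)) {
    pri <- genotype_priors(k, h)
    for (v in seq_along(b)) {
      terms <- vapply(seq_len(nrow(pri)), function(g) {
        if (pri$mass[g] <= 0) return(-Inf)
        log(pri$mass[g]) +
          truncnorm_maf_density(b[v], pri$mu[g], sigma_b, log = TRUE)
      }, numeric(1))
      lp <- lp + logsumexp(terms)
    }
  }
  lp
}

# Vectorized emission log-matrix over all amplicons of a cell.
# obs: list(d, b, b_amp, Vi, h, sumb, sumb2) -- see build_cell_obs().
# comp: maf_mixture_components(K).
# With detail = TRUE also returns the BAF-only log-likelihood per state
# and the per-genotype-component log terms needed for the sigma_b M-step.
emission_matrix <- function(obs, mu, sigma_d2, sigma_b, comp,
                            detail = FALSE) {
  A <- length(obs$d)
  K <- length(mu)
  logE <- matrix(0, A, K)
  od <- !is.na(obs$d)
  if (any(od)) {
    sd_d <- sqrt(sigma_d2)
    for (k in seq_len(K)) {
      logE[od, k] <- stats::dnorm(obs$d[od], mu[k], sd_d, log = TRUE)
    }
  }
  baf_detail <- NULL
  if (length(obs$b)) {
    mus <- sort(unique(unlist(lapply(comp, `[[`, "mu"))))
    # per-variant log truncated-normal density at each candidate MAF mean
    D <- vapply(mus, function(m) {
      z <- stats::pnorm(0.5, m, sigma_b) - stats::pnorm(0, m, sigma_b)
      stats::dnorm(obs$b, m, sigma_b, log = TRUE) - log(z)
    }, numeric(length(obs$b)))
    D <- matrix(D, nrow = length(obs$b))
    hv <- obs$h[obs$b_amp]
    lmix <- matrix(0, length(obs$b), K)  # per-variant genotype mixture
    for (k in seq_len(K)) {
      cm <- comp[[k]]
      cols <- lapply(seq_len(nrow(cm)), function(j) {
        w <- cm$a[j] + cm$b[j] * hv
        lw <- ifelse(w > 0, log(w), -Inf)
        lw + D[, match(cm$mu[j], mus)]
      })
      X <- do.call(cbind, cols)
      mx <- do.call(pmax, cols)
      lmix[, k] <- mx + log(rowSums(exp(X - mx)))
      # per-amplicon sum of per-variant log mixtures
      agg <- rowsum(lmix[, k], group = obs$b_amp)
      logE[as.integer(rownames(agg)), k] <-
        logE[as.integer(rownames(agg)), k] + agg
    }
    if (detail) {
      baf_detail <- list(D = D, mus = mus, lmix = lmix, hv = hv)
    }
  }
  if (detail) list(logE = logE, baf = baf_detail) else logE
}

# Exact M-step for the MAF standard deviation. Each variant's genotype
# components are weighted by their posterior given the observed MAF and
# the state posterior of the host amplicon; with those responsibilities
# fixed, the expected complete-data log-likelihood is maximized over
# sigma_b directly. The truncation normalizer depends on sigma, so the
# maximizer is found by 1-d optimization over the few unique genotype
# means rather than by a moment formula.
baf_sigma_mstep <- function(obs, comp, gamma, baf_detail, current,
                            lower = 1e-3, upper = 0.6) {
  b <- obs$b
  gv <- gamma[obs$b_amp, , drop = FALSE]   # state posteriors per variant
  mus <- baf_detail$mus
  W <- numeric(length(mus))
  SS <- numeric(length(mus))
  for (k in seq_len(ncol(gamma))) {
    cm <- comp[[k]]
    for (j in seq_len(nrow(cm))) {
      w <- cm$a[j] + cm$b[j] * baf_detail$hv
      lw <- ifelse(w > 0, log(w), -Inf)
      u <- match(cm$mu[j], mus)
      r <- gv[, k] * exp(lw + baf_detail$D[, u] - baf_detail$lmix[, k])
      W[u] <- W[u] + sum(r)
      SS[u] <- SS[u] + sum(r * (b - cm$mu[j])^2)
    }
  }
  neg_q <- function(sig) {
    z <- stats::pnorm(0.5, mus, sig) - stats::pnorm(0, mus, sig)
    sum(W * (log(sig) + log(z))) + sum(SS) / (2 * sig^2)
  }
  cand <- stats::optimize(neg_q, c(lower, upper), tol = 1e-6)$minimum
  # generalized EM guard: never accept a value worse than the current one
  if (current >= lower && current <= upper &&
      neg_q(cand) > neg_q(current)) current else cand
}

#' Forward-backward posteriors for one chain
#'
#' Scaled forward-backward recursion over one chromosome's amplicons.
#' Returns state posteriors gamma, transition posteriors xi, and the chain
#' log-likelihood. Emissions are supplied on the log scale and are
#' stabilized per position before exponentiation, so arbitrarily small
#' emission probabilities are handled.
#'
#' @param logE n x K matrix of log emission probabilities.
#' @param Tm K x K transition matrix.
#' @param init initial state distribution (default uniform).
#' @return list with `gamma` (n x K, rows sum to 1), `xi`
#'   ((n-1) x K x K array, each slice sums to 1), and `loglik`.
#' @export
forward_backward <- function(logE, Tm, init = NULL) {
  n <- nrow(logE)
  K <- ncol(logE)
  if (is.null(init)) init <- rep(1 / K, K)
  mx <- apply(logE, 1L, max)
  if (any(!is.finite(mx))) {
    stop("all states impossible at position ", which(!is.finite(mx))[1L])
  }
  E <- exp(logE - mx)
  alpha <- matrix(0, n, K)
  cs <- numeric(n)
  a <- init * E[1L, ]
  cs[1L] <- sum(a)
  if (cs[1L] <= 0) stop("numerical underflow in forward pass at position 1")
  alpha[1L, ] <- a / cs[1L]
  if (n > 1L) {
    for (t in 2:n) {
      a <- as.vector(alpha[t - 1L, ] %*% Tm) * E[t, ]
      cs[t] <- sum(a)
      if (cs[t] <= 0) stop("numerical underflow in forward pass at position ", t)
      alpha[t, ] <- a / cs[t]
    }
  }
  beta <- matrix(1, n, K)
  if (n > 1L) {
    for (t in (n - 1L):1L) {
      beta[t, ] <- as.vector(Tm %*% (E[t + 1L, ] * beta[t + 1L, ])) / cs[t + 1L]
    }
  }
  gamma <- alpha * beta
  xi <- if (n > 1L) {
    x <- array(0, c(n - 1L, K, K))
    for (t in 2:n) {
      x[t - 1L, , ] <- (alpha[t - 1L, ] %o% (E[t, ] * beta[t, ])) * Tm / cs[t]
    }
    x
  }
  list(gamma = gamma, xi = xi, loglik = sum(log(cs)) + sum(mx))
}

# Pooled scaled forward-backward over many chains, grouped by chain length
# so each recursion step is a single matrix operation across chains.
# chains: list of integer row-index vectors into logE.
# Returns gamma aligned to logE rows, the summed off-diagonal transition
# posterior mass, the number of transitions, and the total log-likelihood.
fb_pooled <- function(logE, chains, Tm, init) {
  K <- ncol(logE)
  gamma <- matrix(0, nrow(logE), K)
  loglik <- 0
  offdiag <- 0
  ntrans <- 0L
  tdiag <- diag(Tm)
  tTm <- t(Tm)
  lens <- lengths(chains)
  for (L in unique(lens)) {
    grp <- chains[lens == L]
    m <- length(grp)
    idx <- matrix(unlist(grp), nrow = m, byrow = TRUE)
    Earr <- vector("list", L)
    mxs <- matrix(0, m, L)
    for (t in seq_len(L)) {
      le <- logE[idx[, t], , drop = FALSE]
      mt <- apply(le, 1L, max)
      if (any(!is.finite(mt))) stop("all states impossible within a chain")
      mxs[, t] <- mt
      Earr[[t]] <- exp(le - mt)
    }
    alpha <- vector("list", L)
    cs <- matrix(0, m, L)
    a <- Earr[[1L]] * rep(init, each = m)
    cs[, 1L] <- rowSums(a)
    alpha[[1L]] <- a / cs[, 1L]
    if (L > 1L) {
      for (t in 2:L) {
        a <- (alpha[[t - 1L]] %*% Tm) * Earr[[t]]
        cs[, t] <- rowSums(a)
        if (any(cs[, t] <= 0)) stop("numerical underflow in forward pass")
        alpha[[t]] <- a / cs[, t]
      }
    }
    B <- matrix(1, m, K)
    gamma[idx[, L], ] <- alpha[[L]]
    if (L > 1L) {
      for (t in (L - 1L):1L) {
        EB <- Earr[[t + 1L]] * B
        # off-diagonal xi mass for the transition t -> t+1
        dsum <- rowSums(alpha[[t]] * sweep(EB, 2L, tdiag, "*")) / cs[, t + 1L]
        offdiag <- offdiag + sum(1 - dsum)
        B <- (EB %*% tTm) / cs[, t + 1L]
        gamma[idx[, t], ] <- alpha[[t]] * B
      }
      ntrans <- ntrans + m * (L - 1L)
    }
    loglik <- loglik + sum(log(cs)) + sum(mxs)
  }
  list(gamma = gamma, offdiag = offdiag, ntrans = ntrans, loglik = loglik)
}

#' Viterbi decoding for one chain
#'
#' Most probable state path under the model, computed in log space. Ties
#' break toward the lowest state.
#'
#' @inheritParams forward_backward
#' @return integer state path of length `nrow(logE)`.
#' @export
viterbi_path <- function(logE, Tm, init = NULL) {
  n <- nrow(logE)
  K <- ncol(logE)
  if (is.null(init)) init <- rep(1 / K, K)
  lT <- log(Tm)
  delta <- log(init) + logE[1L, ]
  psi <- matrix(0L, n, K)
  if (n > 1L) {
    for (t in 2:n) {
      cand <- delta + lT  # cand[j, k] = delta[j] + log T[j, k]
      psi[t, ] <- apply(cand, 2L, which.max)
      delta <- cand[cbind(psi[t, ], seq_len(K))] + logE[t, ]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1L) {
    for (t in (n - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  }
  path
}

#' Fit HMM parameters for one cell by Baum-Welch
#'
#' Expectation-maximization over one cell's observations. The E-step runs
#' the forward-backward recursion independently per chromosome; the M-step
#' pools sufficient statistics across chromosomes, since individual
#' chromosomes carry too few amplicons to estimate noise parameters on
#' their own. Updates: state depth means (posterior-weighted average of
#' observed depth), depth variance, MAF standard deviation (posterior- and
#' prior-weighted squared residuals about each state's expected MAF), and
#' the switch rate (off-diagonal transition posterior mass per transition).
#' When the mean heterozygosity across amplicons falls below 0.25 the
#' allele-frequency signal can no longer anchor the states, so the depth
#' means are shrunk toward their prior values k/2 with a pseudo-observation
#' weight that grows as heterozygosity falls.
#'
#' @param obs cell observations from [build_cell_obs()].
#' @param params initial parameter list (`mu`, `sigma_d2`, `sigma_b`,
#'   `epsilon`, `K`).
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the largest absolute parameter
#'   change.
#' @param w0 scale of the low-heterozygosity mean regularization, in units
#'   of depth observations per state: the pseudo-observation weight is
#'   `w0 * n_d * (0.25 - hbar) / 0.25` when the mean heterozygosity hbar
#'   falls below 0.25, zero otherwise. Scaling with the number of depth
#'   observations `n_d` keeps the prior competitive with the posterior
#'   mass, so the state means are effectively pinned at k/2 when no
#'   allelic signal exists to anchor them.
#' @param eps_prior strength of the Beta prior that anchors the switch
#'   rate at its initial value, expressed as a multiple of the observed
#'   transition count. Whole-chromosome events make within-chromosome
#'   breakpoints rare, and a single cell's handful of transitions cannot
#'   overrule that; set to 0 for the plain maximum-likelihood update.
#' @return list with fitted `params`, final `gamma`, per-iteration
#'   `loglik` trace, `n_iter`, and `converged`.
#' @export
baum_welch <- function(obs, params, max_iter = 50L, tol = 1e-5, w0 = 2,
                       eps_prior = 20) {
  eps0 <- params$epsilon
  K <- params$K
  comp <- maf_mixture_components(K)
  init <- rep(1 / K, K)
  hbar <- mean(obs$h)
  od <- !is.na(obs$d)
  nd <- sum(od)
  w <- w0 * nd * max(0.25 - hbar, 0.05) / 0.25
  hasb <- obs$Vi > 0L
  nb <- sum(obs$Vi)
  llks <- numeric(0)
  gamma <- NULL
  for (iter in seq_len(max_iter)) {
    if (!all(is.finite(c(params$mu, params$sigma_d2, params$sigma_b,
                         params$epsilon)))) {
      stop("non-finite parameters at EM iteration ", iter)
    }
    Tm <- transition_matrix(params$epsilon, K)
    em <- emission_matrix(obs, params$mu, params$sigma_d2, params$sigma_b,
                          comp, detail = TRUE)
    logE <- em$logE
    fb <- fb_pooled(logE, obs$chains, Tm, init)
    if (!is.finite(fb$loglik)) {
      stop("non-finite likelihood at EM iteration ", iter)
    }
    llks <- c(llks, fb$loglik)
    gamma <- fb$gamma
    old <- c(params$mu, params$sigma_d2, params$sigma_b, params$epsilon)
    # depth means (optionally regularized toward k/2)
    gd <- gamma[od, , drop = FALSE]
    num <- colSums(gd * obs$d[od])
    den <- colSums(gd)
    mu_new <- params$mu
    for (k in seq_len(K)) {
      if (w > 0) {
        mu_new[k] <- (num[k] + w * k / 2) / (den[k] + w)
      } else if (den[k] > 1e-8) {
        mu_new[k] <- num[k] / den[k]
      } # else: no posterior mass and no prior weight -> keep current value
    }
    params$mu <- mu_new
    # depth variance about the updated means
    if (nd > 0L) {
      resid2 <- sweep(matrix(obs$d[od], nd, K), 2L, mu_new, "-")^2
      params$sigma_d2 <- max(sum(gd * resid2) / nd, 1e-6)
    }
    # MAF standard deviation: exact M-step given genotype responsibilities
    if (nb > 0L) {
      params$sigma_b <- baf_sigma_mstep(obs, comp, gamma, em$baf,
                                        current = params$sigma_b)
    }
    # switch rate (MAP with Beta prior anchored at the initial rate)
    if (fb$ntrans > 0L) {
      rate <- (fb$offdiag / fb$ntrans + eps_prior * eps0) / (1 + eps_prior)
      params$epsilon <- min(max(rate, 1e-8), 1 - 1e-6)
    }
    delta <- max(abs(c(params$mu, params$sigma_d2, params$sigma_b,
                       params$epsilon) - old))
    if (delta < tol) {
      return(list(params = params, gamma = gamma, loglik = llks,
                  n_iter = iter, converged = TRUE))
    }
  }
  list(params = params, gamma = gamma, loglik = llks, n_iter = max_iter,
       converged = FALSE)
}

#' Aggregate per-amplicon states to chromosome calls
#'
#' The call for each chromosome is the modal state across its amplicons.
#' Ties break toward the state closest to diploid, then toward the lower
#' state, so ambiguous segments are called conservatively.
#'
#' @param path integer vector of per-amplicon states.
#' @param chrom chromosome label per amplicon.
#' @return named integer vector of per-chromosome calls, in natural
#'   chromosome order.
#' @export
aggregate_segments <- function(path, chrom) {
  stopifnot(length(path) == length(chrom))
  lev <- chrom_order(chrom)
  out <- vapply(lev, function(ch) {
    s <- path[chrom == ch]
    tab <- table(s)
    cand <- as.integer(names(tab)[tab == max(tab)])
    cand[order(abs(cand - 2L), cand)][1L]
  }, integer(1))
  names(out) <- lev
  out
}

# Assemble one cell's observation bundle from the normalized depth vector
# and MAF vector, using the panel layout prepared by the caller.
# layout: list(chains, amp_chrom, Vi, h, b_amp_all) with b_amp_all mapping
# every variant row to its amplicon index.
build_cell_obs_internal <- function(d, b_all, layout) {
  keep <- !is.na(b_all)
  b <- b_all[keep]
  b_amp <- layout$b_amp_all[keep]
  Vi <- integer(length(d))
  if (length(b)) {
    tb <- tabulate(b_amp, nbins = length(d))
    Vi <- tb
  }
  sumb <- numeric(length(d))
  sumb2 <- numeric(length(d))
  if (length(b)) {
    s1 <- rowsum(b, b_amp)
    s2 <- rowsum(b^2, b_amp)
    sumb[as.integer(rownames(s1))] <- s1
    sumb2[as.integer(rownames(s2))] <- s2
  }
  list(d = d, b = b, b_amp = b_amp, Vi = Vi, h = layout$h,
       sumb = sumb, sumb2 = sumb2, chains = layout$chains)
}

#' Build a cell observation bundle
#'
#' Packages one cell's reference-normalized depth and folded minor allele
#' frequencies into the per-chromosome chain structure consumed by
#' [baum_welch()] and [viterbi_path()].
#'
#' @param d named numeric vector of normalized depth per amplicon, in
#'   genome order (NA allowed).
#' @param maf numeric vector of MAF values per variant (NA allowed).
#' @param variant_amplicon character vector, the host amplicon id of each
#'   variant.
#' @param chrom chromosome label per amplicon.
#' @param h per-amplicon heterozygosity rates.
#' @return observation bundle (list) for the EM routines.
#' @export
build_cell_obs <- function(d, maf, variant_amplicon, chrom, h) {
  amp_ids <- names(d)
  stopifnot(!is.null(amp_ids), length(chrom) == length(d),
            length(h) == length(d))
  b_amp_all <- match(variant_amplicon, amp_ids)
  keep_var <- !is.na(b_amp_all)
  chains <- split(seq_along(d), factor(chrom, levels = chrom_order(chrom)))
  layout <- list(chains = chains, h = h,
                 b_amp_all = b_amp_all[keep_var])
  build_cell_obs_internal(d, maf[keep_var], layout)
}
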