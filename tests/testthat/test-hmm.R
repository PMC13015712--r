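test_that("transition matrix spreads the switch mass evenly", {
  Tm <- transition_matrix(1e-3, 5L)
  expect_equal(diag(Tm), rep(0.999, 5))
  expect_equal(Tm[1, 2], 0.00025)
  expect_equal(transition_matrix(0.8, 2L),
               matrix(c(0.2, 0.8, 0.8, 0.2), 2, 2))
  for (eps in c(0.01, 0.5, 0.99)) {
    expect_equal(rowSums(transition_matrix(eps, 4L)), rep(1, 4))
  }
  expect_error(transition_matrix(0, 5L), "\\(0, 1\\)")
  expect_error(transition_matrix(1.2, 5L), "\\(0, 1\\)")
})

test_that("forward-backward and Viterbi match exhaustive enumeration", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(1:6, 1)
    K <- sample(2:4, 1)
    inst <- random_instance(n, K)
    bf <- bf_hmm(inst$logE, inst$Tm, inst$init)
    fb <- forward_backward(inst$logE, inst$Tm, inst$init)
    expect_equal(fb$gamma, bf$gamma, tolerance = 1e-10)
    expect_equal(fb$loglik, bf$loglik, tolerance = 1e-10)
    if (n > 1) expect_equal(fb$xi, bf$xi, tolerance = 1e-10)
    expect_equal(viterbi_path(inst$logE, inst$Tm, inst$init), bf$viterbi)
  }
})

test_that("posteriors are coherent distributions", {
  set.seed(202)
  inst <- random_instance(5, 4)
  fb <- forward_backward(inst$logE, inst$Tm, inst$init)
  expect_equal(rowSums(fb$gamma), rep(1, 5))
  for (t in 1:4) {
    expect_equal(sum(fb$xi[t, , ]), 1, tolerance = 1e-12)
    # xi margins recover gamma on both sides of each transition
    expect_equal(rowSums(fb$xi[t, , ]), fb$gamma[t, ], tolerance = 1e-12)
    expect_equal(colSums(fb$xi[t, , ]), fb$gamma[t + 1, ], tolerance = 1e-12)
  }
})

test_that("degenerate chains behave sensibly", {
  K <- 3L
  logE <- matrix(log(c(0.2, 0.5, 0.3)), 1, K)
  init <- c(0.6, 0.3, 0.1)
  fb <- forward_backward(logE, transition_matrix(0.1, K), init)
  want <- init * c(0.2, 0.5, 0.3)
  expect_equal(fb$gamma[1, ], want / sum(want))
  # near-zero switch rate: posterior concentrates on one state per chain
  set.seed(7)
  logE2 <- matrix(stats::rnorm(12), 4, K)
  logE2[, 2] <- logE2[, 2] + 5   # clear per-position margin for state 2
  fb2 <- forward_backward(logE2, transition_matrix(1e-12, K))
  expect_true(all(fb2$gamma[, 2] > 1 - 1e-3))
  expect_equal(unique(apply(fb2$gamma, 1, which.max)), 2L)
  # uniform emissions: Viterbi ties break to the lowest state
  expect_equal(viterbi_path(matrix(0, 3, 4), transition_matrix(0.2, 4L)),
               rep(1L, 3))
})

test_that("pooled multi-chain engine equals per-chain recursions", {
  set.seed(303)
  K <- 5L
  lens <- c(4L, 4L, 2L, 6L, 1L, 4L)
  logE <- matrix(stats::rnorm(sum(lens) * K, sd = 1.5), sum(lens), K)
  chains <- split(seq_len(sum(lens)), rep(seq_along(lens), lens))
  Tm <- transition_matrix(0.05, K)
  init <- rep(1 / K, K)
  pooled <- tapcnv:::fb_pooled(logE, chains, Tm, init)
  gamma <- matrix(0, sum(lens), K)
  ll <- 0
  off <- 0
  for (ch in chains) {
    fb <- forward_backward(logE[ch, , drop = FALSE], Tm, init)
    gamma[ch, ] <- fb$gamma
    ll <- ll + fb$loglik
    if (length(ch) > 1) {
      for (t in seq_len(length(ch) - 1)) {
        off <- off + sum(fb$xi[t, , ]) - sum(diag(fb$xi[t, , ]))
      }
    }
  }
  expect_equal(pooled$gamma, gamma, tolerance = 1e-10)
  expect_equal(pooled$loglik, ll, tolerance = 1e-10)
  expect_equal(pooled$offdiag, off, tolerance = 1e-10)
  expect_equal(pooled$ntrans, sum(pmax(lens - 1L, 0L)))
})

test_that("plain EM increases the likelihood monotonically", {
  for (s in 1:50) {
    set.seed(s)
    cell <- random_cell_obs(n_chr = 4L, amp_per_chr = 3L, vpa = 1L,
                            het = stats::runif(1, 0.3, 1),
                            sigma_d = stats::runif(1, 0.2, 0.5))
    fit <- baum_welch(cell$obs, default_params(), max_iter = 25L,
                      w0 = 0, eps_prior = 0)
    expect_true(all(diff(fit$loglik) >= -1e-8),
                info = sprintf("seed %d", s))
  }
})

test_that("EM recovers generative parameters on model data", {
  set.seed(99)
  recov <- replicate(10, {
    cell <- random_cell_obs(n_chr = 22L, amp_per_chr = 4L, vpa = 3L,
                            het = 1, sigma_d = 0.3, sigma_b = 0.07)
    fit <- baum_welch(cell$obs, default_params(sigma_d2 = 0.2,
                                               sigma_b = 0.1))
    vit <- integer(length(cell$obs$d))
    Tm <- transition_matrix(fit$params$epsilon, 5L)
    logE <- tapcnv:::emission_matrix(cell$obs, fit$params$mu,
                                     fit$params$sigma_d2,
                                     fit$params$sigma_b,
                                     tapcnv:::maf_mixture_components(5L))
    for (ch in cell$obs$chains) {
      vit[ch] <- viterbi_path(logE[ch, , drop = FALSE], Tm)
    }
    c(mu_err = max(abs(fit$params$mu - (1:5) / 2)),
      sb = fit$params$sigma_b,
      acc = mean(vit == cell$states))
  })
  expect_lt(mean(recov["mu_err", ]), 0.15)
  expect_lt(abs(mean(recov["sb", ]) - 0.07), 0.3 * 0.07)
  expect_gt(mean(recov["acc", ]), 0.9)
})

test_that("zero heterozygosity keeps means pinned at the prior", {
  set.seed(17)
  cell <- random_cell_obs(n_chr = 8L, amp_per_chr = 4L, vpa = 0L, het = 0,
                          states = rep(2L, 32L))
  fit <- baum_welch(cell$obs, default_params(sigma_d2 = 0.09))
  expect_lt(max(abs(fit$params$mu - (1:5) / 2)), 0.2)
})

test_that("single-state truth keeps the switch rate rare", {
  set.seed(23)
  cell <- random_cell_obs(n_chr = 6L, amp_per_chr = 4L, vpa = 2L, het = 1,
                          states = rep(2L, 24L))
  fit <- baum_welch(cell$obs, default_params())
  expect_lte(fit$params$epsilon, 1e-2)
})

test_that("segment aggregation takes the mode with diploid tie-break", {
  expect_equal(unname(aggregate_segments(c(3L, 3L, 3L, 2L),
                                         rep("1", 4))), 3L)
  # tie between 1 and 3: both one step from diploid, lower wins
  expect_equal(unname(aggregate_segments(c(1L, 1L, 3L, 3L),
                                         rep("1", 4))), 1L)
  # tie between 2 and 4: diploid wins
  expect_equal(unname(aggregate_segments(c(2L, 2L, 4L, 4L),
                                         rep("1", 4))), 2L)
  expect_equal(unname(aggregate_segments(c(2L, 2L, 2L, 2L),
                                         rep("1", 4))), 2L)
  out <- aggregate_segments(c(1L, 1L, 5L), c("10", "10", "2"))
  expect_equal(out, c("2" = 5L, "10" = 1L))
})
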