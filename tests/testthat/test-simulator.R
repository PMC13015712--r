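test_that("amplicon parameters respect the design ranges", {
  set.seed(70)
  p <- make_amplicon_params(200)
  expect_true(all(p$shape >= 0.3))
  expect_true(all(p$scale >= 0.5 & p$scale <= 2.5))
  # scales are rank-inverse to shapes
  expect_equal(stats::cor(p$shape, p$scale, method = "spearman"), -1)
  set.seed(70)
  expect_identical(make_amplicon_params(200), p)
})

test_that("simulated counts scale linearly with copy number", {
  set.seed(71)
  params <- data.frame(shape = c(2, 1.2), scale = c(1, 2))
  truth <- matrix(c(2L, 4L), 2, 1,
                  dimnames = list(c("cell_cn2", "cell_cn4"), "1"))
  truth <- truth[rep(1:2, each = 3000), , drop = FALSE]
  rownames(truth) <- paste0("c", seq_len(nrow(truth)))
  cn <- rep(c(2, 4), each = 3000)
  counts <- simulate_counts(truth, params, c("1", "1"), c("a1", "a2"))
  m2 <- rowMeans(counts[, cn == 2])
  m4 <- rowMeans(counts[, cn == 4])
  expect_equal(unname(m4 / m2), c(2, 2), tolerance = 0.05)
  # closed-form Weibull mean: scale * (CN/2) * gamma(1 + 1/shape)
  expect_equal(unname(m2),
               params$scale * gamma(1 + 1 / params$shape),
               tolerance = 0.05)
})

test_that("genotype evolution and BAF expectations are correct", {
  # no noise: heterozygous diploid sits at BAF 0.5, MAF of a trisomic
  # heterozygote at 1/3 (or 2/3 raw), homozygous stays at 0/1
  sim <- build_study2("gain", seed = 73, baf_sd = 0,
                      cells_per_group = 20L, n_chromosomes = 6L,
                      n_altered = 3L)
  ref_cells <- sim$reference$reference_cells
  ref_baf <- sim$baf[, ref_cells]
  expect_true(all(ref_baf %in% c(0, 0.5, 1)))
  alt_cells <- setdiff(colnames(sim$baf), ref_cells)
  maf <- pmin(sim$baf[, alt_cells], 1 - sim$baf[, alt_cells])
  # fully heterozygous founders: unaltered chromosomes stay at MAF 0.5,
  # trisomic ones at exactly 1/3 whichever allele was duplicated
  expect_true(all(abs(maf - 1 / 3) < 1e-9 | abs(maf - 0.5) < 1e-9))
  expect_gt(mean(abs(maf - 1 / 3) < 1e-9), 0.2)
  # zero heterozygosity: all expected MAF are 0 before noise
  sim0 <- build_study2("gain", seed = 74, baf_sd = 0, het_rate = 0,
                       cells_per_group = 10L, n_chromosomes = 4L,
                       n_altered = 2L)
  expect_true(all(pmin(sim0$baf, 1 - sim0$baf) == 0))
})

test_that("study-1 truth marginals match the design", {
  sim <- build_study1(seed = 75, jitter = FALSE)
  truth <- unclass(sim$truth)
  expect_equal(dim(truth), c(480L, 22L))
  expect_equal(unname(table(sim$population)[c("cn1", "reference", "mixed",
                                              "cn3", "cn4", "cn5")]),
               rep(80L, 6L), ignore_attr = TRUE)
  # reference and mixed populations fully diploid
  expect_true(all(truth[sim$population == "reference", ] == 2L))
  expect_true(all(truth[sim$population == "mixed", ] == 2L))
  # each aneuploid population alters exactly n_altered chromosomes
  for (pop in c("cn1", "cn3", "cn4", "cn5")) {
    cn <- as.integer(sub("cn", "", pop))
    row <- truth[sim$population == pop, ][1, ]
    expect_equal(sum(row == cn), 11L)
    expect_equal(sum(row == 2L), 11L)
  }
  # jitter perturbs population sizes within 10%
  simj <- build_study1(seed = 75, jitter = TRUE)
  sizes <- table(simj$population)
  expect_true(all(sizes >= 72 & sizes <= 88))
})

test_that("replicates are reproducible and differ across seeds", {
  s1 <- build_study2("gain", seed = 76, cells_per_group = 10L,
                     n_chromosomes = 5L, n_altered = 2L)
  s2 <- build_study2("gain", seed = 76, cells_per_group = 10L,
                     n_chromosomes = 5L, n_altered = 2L)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$baf, s2$baf)
  expect_identical(unclass(s1$truth), unclass(s2$truth))
  s3 <- build_study2("gain", seed = 77, cells_per_group = 10L,
                     n_chromosomes = 5L, n_altered = 2L)
  expect_false(identical(s1$counts, s3$counts))
  a1 <- build_study1(seed = 80)$altered
  a2 <- build_study1(seed = 81)$altered
  expect_false(identical(a1, a2))
})

test_that("study-2 design places the stated alteration load", {
  g <- build_study2("gain", seed = 78)
  truth <- unclass(g$truth)
  alt <- truth[g$population == "altered", ]
  expect_equal(sum(alt[1, ] == 3L), 7L)
  expect_true(all(truth[g$population == "reference", ] == 2L))
  l <- build_study2("loss", seed = 79)
  alt_l <- unclass(l$truth)[l$population == "altered", ]
  expect_equal(sum(alt_l[1, ] == 1L), 7L)
})

test_that("simulation datasets round-trip through the file formats", {
  sim <- tiny_sim(seed = 82, cells_per_group = 8L, n_chromosomes = 3L)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_setequal(list.files(dir),
                  c("counts.tsv", "baf.tsv", "panel.tsv", "variants.tsv",
                    "reference.json", "truth.tsv"))
  counts <- read_count_matrix(file.path(dir, "counts.tsv"))
  expect_equal(unclass(counts), unclass(sim$counts), tolerance = 1e-9)
  truth <- read_callset(file.path(dir, "truth.tsv"))
  expect_equal(unclass(truth)[, ], unclass(sim$truth)[, ])
})
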