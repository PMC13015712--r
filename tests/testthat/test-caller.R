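test_that("HMM caller recovers strong signals end to end", {
  sim <- tiny_sim(seed = 501, cells_per_group = 30L)
  fit <- suppressWarnings(call_cnv_hmm(sim$counts, sim$baf, sim$panel,
                                       sim$reference))
  expect_s3_class(fit, "cnv_hmm_fit")
  tr <- unclass(sim$truth)[rownames(fit$calls), colnames(fit$calls)]
  m <- cnv_metrics(cnv_confusion(fit$calls, tr))
  expect_gt(m$accuracy, 0.9)
  # reference cells called on themselves come out diploid
  ref <- intersect(sim$reference$reference_cells, rownames(fit$calls))
  expect_gt(mean(unclass(fit$calls)[ref, ] == 2L), 0.95)
  expect_output(print(fit), "HMM copy-number fit")
  expect_output(print(summary(fit)), "Altered")
  expect_equal(colnames(coef(fit))[1:5], paste0("mu", 1:5))
})

test_that("depth-only mode still calls (factor-drop contract)", {
  sim <- tiny_sim(seed = 502, cells_per_group = 25L,
                  variants_per_amplicon = 0L)
  expect_null(sim$baf)
  fit <- suppressWarnings(call_cnv_hmm(sim$counts, NULL, sim$panel,
                                       sim$reference))
  expect_equal(ncol(fit$calls), 8L)
  expect_true(all(unclass(fit$calls) %in% 1:5))
  # with no variants the heterozygosity estimates are all zero
  expect_true(all(fit$reference$het_rates == 0))
})

test_that("depth signal contributes: dropping variants does not help", {
  seeds <- c(511L, 512L)
  acc <- function(use_baf, s) {
    sim <- tiny_sim(seed = s, cells_per_group = 25L)
    fit <- suppressWarnings(call_cnv_hmm(
      sim$counts, if (use_baf) sim$baf else NULL, sim$panel,
      sim$reference))
    tr <- unclass(sim$truth)[rownames(fit$calls), colnames(fit$calls)]
    mean(unclass(fit$calls) == tr)
  }
  with_baf <- vapply(seeds, function(s) acc(TRUE, s), numeric(1))
  without <- vapply(seeds, function(s) acc(FALSE, s), numeric(1))
  expect_true(all(without <= with_baf))
})

test_that("caller validates its inputs", {
  sim <- tiny_sim(seed = 503, cells_per_group = 20L)
  bad_ref <- reference_spec("not_a_cell")
  expect_error(
    suppressWarnings(call_cnv_hmm(sim$counts, sim$baf, sim$panel, bad_ref)),
    "reference cells")
})

test_that("trisomic reference template is honored", {
  # simulate a reference population that genuinely carries a trisomy on
  # one chromosome, declared in the template; calls on reference cells
  # should then report 3 there, not 2
  set.seed(504)
  pops <- data.frame(name = c("reference", "other"),
                     cn = c(2L, 2L), cells = c(50L, 10L), mixed = FALSE)
  sim <- simulate_dataset(pops, n_chromosomes = 6L, n_altered = 0L,
                          amplicons_per_chr = 6L,
                          variants_per_amplicon = 0L)
  truth <- unclass(sim$truth)
  truth[, "3"] <- 3L   # everyone trisomic on chromosome 3
  panel_sorted <- sort_panel(sim$panel)
  sim$counts <- simulate_counts(callset(truth), sim$amplicon_params,
                                panel_sorted$amplicons$chrom,
                                panel_sorted$amplicons$amplicon_id)
  spec <- reference_spec(sim$reference$reference_cells, c("3" = 3L))
  fit <- suppressWarnings(call_cnv_hmm(sim$counts, NULL, sim$panel, spec))
  calls3 <- unclass(fit$calls)[, "3"]
  other <- unclass(fit$calls)[, colnames(fit$calls) != "3"]
  # the trisomic chromosome is called higher than the diploid rest
  expect_gt(mean(calls3 == 3L), 0.5)
  expect_gt(mean(calls3 == 3L), mean(other == 3L) + 0.3)
})

test_that("command line interface drives the full pipeline", {
  dir <- withr::local_tempdir()
  code <- cli_main(c("simulate", "--study", "2", "--direction", "gain",
                     "--cells", "20", "--seed", "11", "--out", dir))
  expect_equal(code, 0L)
  expect_true(all(c("counts.tsv", "baf.tsv", "panel.tsv", "variants.tsv",
                    "reference.json", "truth.tsv", "manifest.json") %in%
                    list.files(dir)))
  # determinism: identical bytes on re-run
  dir2 <- withr::local_tempdir()
  cli_main(c("simulate", "--study", "2", "--direction", "gain",
             "--cells", "20", "--seed", "11", "--out", dir2))
  expect_identical(readLines(file.path(dir, "counts.tsv")),
                   readLines(file.path(dir2, "counts.tsv")))
  calls_path <- file.path(dir, "calls.tsv")
  code <- suppressWarnings(cli_main(
    c("call-hmm", "--counts", file.path(dir, "counts.tsv"),
      "--baf", file.path(dir, "baf.tsv"),
      "--panel", file.path(dir, "panel.tsv"),
      "--variants", file.path(dir, "variants.tsv"),
      "--reference", file.path(dir, "reference.json"),
      "--out", calls_path)))
  expect_equal(code, 0L)
  metrics_path <- file.path(dir, "metrics.json")
  code <- cli_main(c("evaluate", "--calls", calls_path,
                     "--truth", file.path(dir, "truth.tsv"),
                     "--out", metrics_path))
  expect_equal(code, 0L)
  met <- jsonlite::read_json(metrics_path)
  expect_gt(met$accuracy, 0.8)
  # usage errors exit non-zero with a one-line diagnostic
  suppressWarnings(
    expect_message(code <- cli_main(c("call-hmm", "--counts",
                                      "missing.tsv")),
                   "tapcnv:"))
  expect_equal(code, 1L)
  expect_message(code <- cli_main("frobnicate"), "unknown subcommand")
  expect_equal(code, 1L)
})
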