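#' Draw per-amplicon Weibull parameters
#'
#' Amplicon capture efficiencies are heterogeneous: shapes are drawn as
#' k_i = max(0.3, N(2, 0.8^2) + 0.3) and scales are constructed inversely
#' related to the shapes (1 / k_i) and min-max rescaled to \[0.5, 2.5\].
#' One draw is shared across all cell populations so amplicon-specific
#' biases are preserved between cell lines.
#'
#' @param n_amplicons number of amplicons.
#' @return data.frame with columns `shape`, `scale`.
#' @export
make_amplicon_params <- function(n_amplicons) {
  shape <- pmax(0.3, stats::rnorm(n_amplicons, 2, 0.8) + 0.3)
  raw <- 1 / shape
  scale <- if (n_amplicons > 1L && diff(range(raw)) > 0) {
    0.5 + 2 * (raw - min(raw)) / (max(raw) - min(raw))
  } else {
    rep(1.5, n_amplicons)
  }
  data.frame(shape = shape, scale = scale)
}

#' Simulate read counts from ground truth
#'
#' Counts for amplicon i in cell c are drawn from a Weibull with the
#' amplicon's shape and scale scaled by CN / 2, so the expected count is
#' proportional to the cell's copy number on that amplicon's chromosome.
#' By default draws are kept continuous: the scale regime of the design
#' puts typical per-amplicon means near one read, where integer rounding
#' would add quantization noise comparable to the biological signal
#' spacing itself; continuous values represent the post-normalization
#' count scale. Set `round_counts = TRUE` to emit integer reads.
#'
#' @param truth cells x chromosomes integer copy-number matrix.
#' @param params data.frame from [make_amplicon_params()].
#' @param amp_chrom chromosome label per amplicon.
#' @param amp_ids amplicon identifiers.
#' @param round_counts round draws to the nearest integer.
#' @return raw count matrix (amplicons x cells).
#' @export
simulate_counts <- function(truth, params, amp_chrom, amp_ids,
                            round_counts = FALSE) {
  A <- nrow(params)
  C <- nrow(truth)
  cn <- t(truth)[amp_chrom, , drop = FALSE]  # A x C copy number
  scale_mat <- params$scale * cn / 2
  d <- stats::rweibull(A * C, shape = rep(params$shape, C),
                       scale = as.vector(scale_mat))
  if (round_counts) d <- round(d)
  m <- matrix(d, A, C, dimnames = list(amp_ids, rownames(truth)))
  count_matrix(m)
}

# Evolve founder diploid B-allele counts to a target copy number by
# sequentially duplicating (gain) or deleting (loss) a uniformly chosen
# existing allele copy. nB: vector of B-allele copies out of `tot`.
evolve_genotype <- function(nB, cn) {
  if (!length(nB)) return(integer())
  tot <- rep(2L, length(nB))
  while (cn > tot[1L]) {
    nB <- nB + stats::rbinom(length(nB), 1L, nB / tot)
    tot <- tot + 1L
  }
  while (cn < tot[1L]) {
    nB <- nB - stats::rbinom(length(nB), 1L, nB / tot)
    tot <- tot - 1L
  }
  nB
}

# Founder diploid B-allele copy counts: heterozygous (1 of 2) with
# probability het_rate, otherwise homozygous AA or BB with equal odds.
draw_founder <- function(n, het_rate) {
  het <- stats::rbinom(n, 1L, het_rate) == 1L
  ifelse(het, 1L, 2L * stats::rbinom(n, 1L, 0.5))
}

#' Simulate a complete dataset with known ground truth
#'
#' Generates a panel, raw counts, B-allele frequencies, a reference
#' specification, and the true copy-number matrix for a set of cell
#' populations. Founder genotypes are drawn once per population (clonal
#' cell-line behavior); populations flagged `mixed` redraw genotypes per
#' cell. Altered-chromosome genotypes are derived from the founder by
#' sequential allele duplication or deletion. Observed BAF is the expected
#' B-allele fraction plus Gaussian noise of standard deviation
#' `baf_sd / 100`, clamped to \[0, 1\].
#'
#' @param populations data.frame with columns `name`, `cn`, `cells`, and
#'   `mixed` (logical).
#' @param n_chromosomes,amplicons_per_chr,variants_per_amplicon panel
#'   dimensions.
#' @param baf_sd BAF noise standard deviation on the percent scale.
#' @param het_rate founder heterozygosity rate.
#' @param n_altered altered chromosomes per non-diploid population (drawn
#'   independently per population).
#' @param reference_population name of the population used as reference
#'   cells.
#' @return list with `counts`, `baf`, `panel`, `reference`, `truth` (a
#'   `callset`), `population` (per-cell labels), and the realized
#'   simulation settings.
#' @export
simulate_dataset <- function(populations,
                             n_chromosomes = 22L,
                             amplicons_per_chr = 4L,
                             variants_per_amplicon = 3L,
                             baf_sd = 9,
                             het_rate = 1,
                             n_altered = 7L,
                             round_counts = FALSE,
                             reference_population = "reference") {
  chroms <- as.character(seq_len(n_chromosomes))
  amp <- expand.grid(j = seq_len(amplicons_per_chr), chrom = chroms,
                     stringsAsFactors = FALSE)
  amp_ids <- sprintf("chr%s_amp%d", amp$chrom, amp$j)
  panel_amp <- data.frame(
    amplicon_id = amp_ids, chrom = amp$chrom,
    start = (amp$j - 1L) * 1000L + 1L, end = amp$j * 1000L)
  A <- nrow(panel_amp)
  if (variants_per_amplicon > 0L) {
    var <- expand.grid(v = seq_len(variants_per_amplicon),
                       ai = seq_len(A))
    variants <- data.frame(
      variant_id = sprintf("%s_v%d", amp_ids[var$ai], var$v),
      amplicon_id = amp_ids[var$ai],
      pos = (var$ai - 1L) * 1000L + var$v * 10L)
  } else {
    variants <- NULL
  }
  panel <- amplicon_panel(panel_amp, variants)
  params <- make_amplicon_params(A)
  nvar <- if (is.null(variants)) 0L else nrow(variants)
  var_chrom <- if (nvar) panel_amp$chrom[match(variants$amplicon_id,
                                               amp_ids)]
  # population structure and truth
  cell_ids <- character()
  pop_of_cell <- character()
  truth_rows <- list()
  altered_sets <- list()
  for (p in seq_len(nrow(populations))) {
    pop <- populations[p, ]
    ids <- sprintf("%s_c%03d", pop$name, seq_len(pop$cells))
    cn_row <- rep(2L, n_chromosomes)
    alt <- character()
    if (pop$cn != 2L) {
      alt <- sample(chroms, n_altered)
      cn_row[match(alt, chroms)] <- as.integer(pop$cn)
    }
    altered_sets[[pop$name]] <- alt
    truth_rows[[p]] <- matrix(cn_row, nrow = pop$cells,
                              ncol = n_chromosomes, byrow = TRUE)
    cell_ids <- c(cell_ids, ids)
    pop_of_cell <- c(pop_of_cell, rep(pop$name, pop$cells))
  }
  truth <- do.call(rbind, truth_rows)
  dimnames(truth) <- list(cell_ids, chroms)
  counts <- simulate_counts(truth, params, panel_amp$chrom, amp_ids,
                            round_counts = round_counts)
  # genotypes and BAF
  baf <- NULL
  if (nvar) {
    expected <- matrix(NA_real_, nvar, length(cell_ids))
    for (p in seq_len(nrow(populations))) {
      pop <- populations[p, ]
      cols <- which(pop_of_cell == pop$name)
      alt <- altered_sets[[pop$name]]
      on_alt <- var_chrom %in% alt
      if (pop$mixed) {
        for (cc in cols) {
          expected[, cc] <- draw_founder(nvar, het_rate) / 2
        }
      } else {
        nB2 <- draw_founder(nvar, het_rate)
        ebaf <- nB2 / 2
        if (length(alt) && pop$cn != 2L) {
          nB_alt <- evolve_genotype(nB2[on_alt], as.integer(pop$cn))
          ebaf[on_alt] <- nB_alt / pop$cn
        }
        expected[, cols] <- ebaf
      }
    }
    noise <- matrix(stats::rnorm(nvar * length(cell_ids), 0, baf_sd / 100),
                    nvar, length(cell_ids))
    obs <- pmin(pmax(expected + noise, 0), 1)
    dimnames(obs) <- list(variants$variant_id, cell_ids)
    baf <- baf_table(obs)
  }
  ref_cells <- cell_ids[pop_of_cell == reference_population]
  list(counts = counts, baf = baf, panel = panel,
       reference = reference_spec(ref_cells),
       truth = callset(truth),
       population = structure(pop_of_cell, names = cell_ids),
       amplicon_params = params,
       altered = altered_sets,
       settings = list(n_chromosomes = n_chromosomes,
                       amplicons_per_chr = amplicons_per_chr,
                       variants_per_amplicon = variants_per_amplicon,
                       baf_sd = baf_sd, het_rate = het_rate,
                       n_altered = n_altered))
}

#' Build a study-1 style dataset (balanced multi-state design)
#'
#' Six equal-sized cell populations: monosomy (CN 1), a diploid reference,
#' a diploid "mixed" population with per-cell genotypes, trisomy (CN 3),
#' tetrasomy (CN 4), and pentasomy (CN 5). Each aneuploid population
#' independently alters a random subset of `n_altered` (default 11, half)
#' of the 22 chromosomes. Optional replicate jitter multiplies population sizes by
#' Uniform(0.9, 1.1) and the BAF noise sd by Uniform(0.85, 1.15).
#'
#' @param seed RNG seed for the replicate.
#' @param cells_per_group nominal population size.
#' @param jitter apply the replicate jitter.
#' @param ... panel and noise settings passed to [simulate_dataset()].
#' @return see [simulate_dataset()].
#' @export
build_study1 <- function(seed, cells_per_group = 80L, jitter = TRUE,
                         baf_sd = 9, n_altered = 11L, ...) {
  set.seed(seed)
  n6 <- rep(cells_per_group, 6L)
  if (jitter) {
    n6 <- round(n6 * stats::runif(6L, 0.9, 1.1))
    baf_sd <- baf_sd * stats::runif(1L, 0.85, 1.15)
  }
  pops <- data.frame(
    name = c("cn1", "reference", "mixed", "cn3", "cn4", "cn5"),
    cn = c(1L, 2L, 2L, 3L, 4L, 5L),
    cells = n6,
    mixed = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  simulate_dataset(pops, baf_sd = baf_sd, n_altered = n_altered, ...)
}

#' Build a study-2 style dataset (two-population design)
#'
#' A diploid reference population plus one altered cell line carrying a
#' uniform gain (CN 3) or loss (CN 1) on `n_altered` of 22 chromosomes.
#' Baseline settings: BAF sd 9, 3 variants per amplicon, 4 amplicons per
#' chromosome, 100 cells per group, 100% heterozygosity; vary one at a
#' time via the arguments.
#'
#' @param direction "gain" (CN 3) or "loss" (CN 1).
#' @param seed RNG seed for the replicate.
#' @param cells_per_group cells in each of the two populations.
#' @param ... panel and noise settings passed to [simulate_dataset()].
#' @return see [simulate_dataset()].
#' @export
build_study2 <- function(direction = c("gain", "loss"), seed,
                         cells_per_group = 100L, ...) {
  direction <- match.arg(direction)
  set.seed(seed)
  pops <- data.frame(
    name = c("reference", "altered"),
    cn = c(2L, if (direction == "gain") 3L else 1L),
    cells = rep(cells_per_group, 2L),
    mixed = FALSE)
  simulate_dataset(pops, ...)
}

#' Write a simulated dataset to a directory
#'
#' Emits counts.tsv, baf.tsv (when variants exist), panel.tsv,
#' variants.tsv, reference.json, and truth.tsv.
#'
#' @param sim list from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_matrix(sim$counts, file.path(dir, "counts.tsv"))
  if (!is.null(sim$baf)) {
    write_baf_table(sim$baf, file.path(dir, "baf.tsv"))
  }
  write_panel(sim$panel, file.path(dir, "panel.tsv"),
              file.path(dir, "variants.tsv"))
  write_reference_spec(sim$reference, file.path(dir, "reference.json"))
  write_callset(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
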